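#' Functional local Bayes factor from the functional local FDR
#'
#' Converts a functional local FDR into a Bayes factor for association:
#'
#'   BF(p, z) = pi0 / (1 - pi0) * (1 - Lambda(p, z)) / Lambda(p, z)
#'
#' the posterior odds of association divided by the prior odds. A local
#' FDR of 1 gives BF = 0; the local FDR floor keeps the result finite.
#'
#' @param pi0_overall Overall proportion of truly null tests, strictly
#'   inside (0, 1) (prior odds are undefined at the boundaries).
#' @param lfdr Functional local FDR values in `[lfdr_floor, 1]`.
#' @return Nonnegative Bayes factors.
#' @export
local_bayes_factor <- function(pi0_overall, lfdr) {
  if (!is.finite(pi0_overall) || pi0_overall <= 0 || pi0_overall >= 1) {
    stop("'pi0_overall' must lie strictly in (0, 1)", call. = FALSE)
  }
  (pi0_overall / (1 - pi0_overall)) * (1 - lfdr) / lfdr
}

#' Single-causal-variant posterior probabilities and credible set
#'
#' Under the assumption of exactly one causal variant in a region with a
#' uniform prior over the L variants, the posterior probability of the
#' i-th variant is its Bayes factor divided by the sum of Bayes factors in
#' the region. The credible set is the smallest set of variants, taken in
#' descending posterior probability (ties broken by input order), whose
#' cumulative posterior mass reaches `credible_mass`.
#'
#' @param bf Nonnegative Bayes factors, at least one positive.
#' @param snp_ids Optional variant identifiers (defaults to positional).
#' @param credible_mass Target posterior mass of the credible set
#'   (default 0.95).
#' @param region_id Optional region label carried into the result.
#' @return An object of class `region_posterior` with elements
#'   `region_id`, `snp_ids`, `bf`, `pp` (summing to 1), `credible_set`
#'   (identifiers, in descending-pp order), and `credible_mass`.
#' @export
region_posterior <- function(bf, snp_ids = NULL, credible_mass = 0.95,
                             region_id = NA_character_) {
  L <- length(bf)
  if (L == 0L) stop("empty region", call. = FALSE)
  if (any(!is.finite(bf) | bf < 0)) stop("'bf' must be finite and nonnegative", call. = FALSE)
  if (all(bf == 0)) stop("no signal in region: all Bayes factors are zero", call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(L))
  pp <- bf / sum(bf)
  o <- order(-pp)  # stable: ties keep input order
  cum <- cumsum(pp[o])
  n_cs <- which(cum >= credible_mass - 1e-12)[1L]
  if (is.na(n_cs)) n_cs <- L
  structure(list(
    region_id = region_id,
    snp_ids = snp_ids,
    bf = bf,
    pp = pp,
    credible_set = snp_ids[o[seq_len(n_cs)]],
    credible_mass = credible_mass),
    class = "region_posterior")
}

#' Fine-map regions from sfFDR results
#'
#' Computes functional local Bayes factors and single-causal-variant
#' posterior probabilities for each supplied region. Regions are given
#' either as a BED-like table (`region_id`, `chr`, `start`, `end`;
#' 0-based half-open) matched against the result's chromosome/position
#' columns, or as windows of `window_kb` kilobases around lead SNPs when
#' `regions` is omitted (lead SNP = smallest functional local FDR among
#' SNPs with `lfdr_f` below `lead_lfdr`, greedily, skipping SNPs already
#' assigned).
#'
#' @param results A per-SNP results table with columns `snp`, `chr`,
#'   `pos`, `lfdr_f` (as produced by [sffdr()] / [run_sffdr()]).
#' @param regions Optional region table (`region_id`, `chr`, `start`,
#'   `end`).
#' @param pi0_overall Overall null proportion entering the Bayes factor;
#'   defaults to the attribute stored on `results`.
#' @param credible_mass Credible-set mass (default 0.95).
#' @param window_kb Half-window around lead SNPs when `regions` is absent
#'   (default 500).
#' @param lead_lfdr Local-FDR cutoff defining lead SNPs (default 0.01).
#' @return A `data.table` with one row per SNP per region: `region_id`,
#'   `snp`, `bf`, `pp`, `in_credible_set`.
#' @export
finemap_regions <- function(results, regions = NULL, pi0_overall = NULL,
                            credible_mass = 0.95, window_kb = 500,
                            lead_lfdr = 0.01) {
  if (is.null(pi0_overall)) pi0_overall <- attr(results, "pi0_overall")
  if (is.null(pi0_overall)) stop("supply 'pi0_overall'", call. = FALSE)
  if (!all(c("snp", "lfdr_f") %in% names(results))) {
    stop("'results' must have columns 'snp' and 'lfdr_f'", call. = FALSE)
  }
  if (is.null(regions)) {
    if (anyNA(results$chr) || anyNA(results$pos)) {
      stop("window-based regions need complete 'chr' and 'pos'; supply 'regions'",
           call. = FALSE)
    }
    cand <- which(results$lfdr_f <= lead_lfdr)
    cand <- cand[order(results$lfdr_f[cand])]
    taken <- logical(nrow(results))
    regions <- list()
    for (i in cand) {
      if (taken[i]) next
      w <- which(results$chr == results$chr[i] &
                   abs(results$pos - results$pos[i]) <= window_kb * 1000)
      taken[w] <- TRUE
      regions[[length(regions) + 1L]] <- data.table::data.table(
        region_id = results$snp[i],
        chr = results$chr[i],
        start = max(0L, results$pos[i] - as.integer(window_kb * 1000)),
        end = results$pos[i] + as.integer(window_kb * 1000) + 1L)
    }
    if (length(regions) == 0L) {
      stop("no lead SNPs at lfdr <= ", lead_lfdr, call. = FALSE)
    }
    regions <- data.table::rbindlist(regions)
  }
  out <- vector("list", nrow(regions))
  for (j in seq_len(nrow(regions))) {
    sel <- which(results$chr == regions$chr[j] &
                   results$pos >= regions$start[j] &
                   results$pos < regions$end[j])
    if (length(sel) == 0L) next
    bf <- local_bayes_factor(pi0_overall, results$lfdr_f[sel])
    if (all(bf == 0)) {
      warning(sprintf("region %s has no signal (all local FDRs are 1); skipped",
                      regions$region_id[j]), call. = FALSE)
      next
    }
    rp <- region_posterior(bf, snp_ids = results$snp[sel],
                           credible_mass = credible_mass,
                           region_id = as.character(regions$region_id[j]))
    out[[j]] <- data.table::data.table(
      region_id = rp$region_id, snp = rp$snp_ids, bf = rp$bf, pp = rp$pp,
      in_credible_set = rp$snp_ids %in% rp$credible_set)
  }
  data.table::rbindlist(out)
}

#' @export
print.region_posterior <- function(x, ...) {
  cat(sprintf("region %s: %d variants, %d in the %.0f%% credible set\n",
              x$region_id, length(x$snp_ids), length(x$credible_set),
              100 * x$credible_mass))
  invisible(x)
}
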