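#' Configuration for the synthetic GWAS generator
#'
#' Encodes the generative model used throughout the package's benchmarks:
#' m independent SNPs with a primary study and d informative studies. Each
#' informative study k draws its null proportion
#' pi0^(k) ~ Uniform[1 - gamma, 1 - gamma/2]; its first
#' round(m * (1 - pi0^(k))) SNPs are alternative with P values from
#' Beta(alpha, 5) and the rest null with Uniform(0, 1), so the
#' informative studies' non-null sets are nested index prefixes — SNPs
#' where the pleiotropic signal is shared across the informative traits.
#' The informative
#' P values z shape the primary study through
#'
#'   phi_k(z_k) = baseline * (z_k / pi0^(k))^a   (alternative k, z_k < pi0^(k))
#'              = baseline                        (otherwise)
#'   pi0(z)   = mean_k phi_k(z_k)
#'   omega_k  = z_k / pi0^(k) (alternative k, z_k < pi0^(k)), else 1
#'   alpha(z) = alpha0 - c * (1 - mean_k omega_k)
#'
#' Primary status H ~ Bernoulli(1 - pi0(z)); the primary P value is
#' Uniform(0, 1) under H = 0 and Beta(alpha(z), 5) under H = 1. With
#' `effect_strength = "none"` the informative data carry no signal about
#' the primary study: pi0(z) = baseline and alpha(z) = alpha0.
#'
#' @param m Number of independent SNPs (default 150000).
#' @param d Number of informative studies (default 3).
#' @param gamma Overlap parameter: each informative study's alternative
#'   fraction lies in `[gamma/2, gamma]` (default 0.025, a sparse overlap).
#' @param baseline Baseline null prior for the primary study (default 0.98).
#' @param primary_strength `"high"`, `"medium"`, `"low"` mapping to
#'   alpha0 = 0.3, 0.4, 0.5 (smaller alpha0 = more extreme alternative
#'   P values = more power).
#' @param informative_strength `"high"`, `"medium"`, `"low"` mapping to
#'   the informative Beta shape alpha = 2, 3, 4.
#' @param effect_strength `"large"`, `"moderate"`, `"none"` mapping to
#'   a = 0.6, 0.3, 0 and c = alpha0/2, alpha0/4, 0.
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 150000L, d = 3L, gamma = 0.025, baseline = 0.98,
                       primary_strength = c("medium", "high", "low"),
                       informative_strength = c("high", "medium", "low"),
                       effect_strength = c("large", "moderate", "none"),
                       seed = 1L) {
  primary_strength <- match.arg(primary_strength)
  informative_strength <- match.arg(informative_strength)
  effect_strength <- match.arg(effect_strength)
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)", call. = FALSE)
  if (baseline <= 0 || baseline >= 1) stop("'baseline' must lie in (0, 1)", call. = FALSE)
  alpha0 <- c(high = 0.3, medium = 0.4, low = 0.5)[[primary_strength]]
  alpha_inf <- c(high = 2, medium = 3, low = 4)[[informative_strength]]
  a <- c(large = 0.6, moderate = 0.3, none = 0)[[effect_strength]]
  cc <- switch(effect_strength,
               large = alpha0 / 2, moderate = alpha0 / 4, none = 0)
  structure(list(
    m = as.integer(m), d = as.integer(d), gamma = gamma, baseline = baseline,
    primary_strength = primary_strength,
    informative_strength = informative_strength,
    effect_strength = effect_strength,
    alpha0 = alpha0, alpha_inf = alpha_inf, a = a, c = cc,
    seed = as.integer(seed)),
    class = "sim_config")
}

# round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate independent SNPs from the generative model
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_dataset` with elements `study` (a
#'   `study_table` of primary P values and informative z), and `truth`: a
#'   data.table with per-SNP `H` (0/1 primary status), `pi0_z_true`,
#'   `alpha_z_true`, per-study indicators `H_k_1..H_k_d`, plus attributes
#'   `pi0_k` (per-study null proportions) and the `sim_config`.
#' @export
simulate_independent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m; d <- config$d
  with_seed(substream_seed(config$seed, "simulate"), {
    pi0_k <- stats::runif(d, 1 - config$gamma, 1 - config$gamma / 2)
    z <- matrix(0, m, d)
    Hk <- matrix(0L, m, d)
    for (k in seq_len(d)) {
      n_alt <- as.integer(round_half_away(m * (1 - pi0_k[k])))
      Hk[seq_len(n_alt), k] <- 1L
      z[, k] <- c(stats::rbeta(n_alt, config$alpha_inf, 5),
                  stats::runif(m - n_alt))
    }
    if (config$effect_strength == "none") {
      pi0_z <- rep(config$baseline, m)
      alpha_z <- rep(config$alpha0, m)
    } else {
      phi <- matrix(config$baseline, m, d)
      omega <- matrix(1, m, d)
      for (k in seq_len(d)) {
        act <- Hk[, k] == 1L & z[, k] < pi0_k[k]
        ratio <- z[act, k] / pi0_k[k]
        phi[act, k] <- config$baseline * ratio^config$a
        omega[act, k] <- ratio
      }
      pi0_z <- rowMeans(phi)
      alpha_z <- config$alpha0 - config$c * (1 - rowMeans(omega))
    }
    if (any(alpha_z <= 0)) stop("alpha(z) <= 0; invalid configuration", call. = FALSE)
    H <- as.integer(stats::runif(m) < 1 - pi0_z)
    p <- stats::runif(m)
    n_alt_primary <- sum(H)
    if (n_alt_primary > 0L) {
      p[H == 1L] <- stats::rbeta(n_alt_primary, alpha_z[H == 1L], 5)
    }
    p <- pmax(p, .Machine$double.xmin)  # Beta draws can underflow to 0
    z <- pmax(z, .Machine$double.xmin)

    truth <- data.table::data.table(H = H, pi0_z_true = pi0_z,
                                    alpha_z_true = alpha_z)
    for (k in seq_len(d)) truth[[paste0("H_k_", k)]] <- Hk[, k]
    ds <- list(study = study_table(p, z), truth = truth, pi0_k = pi0_k,
               config = config)
    class(ds) <- "sim_dataset"
    ds
  })
}

#' Oracle functional local FDR of a simulated dataset
#'
#' The exact posterior null probability under the generative model:
#' Lambda = pi0(z) / f(p | z) with
#' f(p | z) = pi0(z) + (1 - pi0(z)) * dbeta(p, alpha(z), 5). Feeding these
#' into [qf_values()] / [pf_values()] yields the oracle q_f and p_f.
#'
#' @param dataset A `sim_dataset`.
#' @return Numeric vector of exact local FDRs.
#' @export
oracle_local_fdr <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  p <- dataset$study$p
  pi0 <- dataset$truth$pi0_z_true
  f1 <- stats::dbeta(p, dataset$truth$alpha_z_true, 5)
  pmin(pi0 / (pi0 + (1 - pi0) * f1), 1)
}

#' Truncated-geometric LD block-size sampler
#'
#' Default stand-in for an empirical LD-block-size distribution: a
#' geometric distribution shifted to start at 1, truncated at `cap`.
#'
#' @param mean_size Target mean block size (default 2.4).
#' @param cap Maximum block size (default 50).
#' @return A function `n -> integer vector of n block sizes`.
#' @export
block_size_sampler <- function(mean_size = 2.4, cap = 50L) {
  if (mean_size < 1) stop("'mean_size' must be >= 1", call. = FALSE)
  prob <- 1 / mean_size  # E[1 + Geom(prob)] = 1/prob
  function(n) pmin(1L + stats::rgeom(n, prob), as.integer(cap))
}

#' Expand a simulated dataset into perfectly correlated LD blocks
#'
#' Each independent SNP i is replicated s_i times with identical primary
#' and informative P values (and identical truth), an extreme model of LD
#' in which every block is perfectly correlated. The originating SNP index
#' is recorded as `block_id` so one representative per block can be
#' selected for training.
#'
#' @param dataset A `sim_dataset` from [simulate_independent()].
#' @param sampler A block-size sampler as from [block_size_sampler()], or
#'   a fixed integer vector of length m.
#' @param seed Integer seed for the block-size draws.
#' @return A `sim_dataset` whose `study` has duplicated rows and a
#'   `block_id` column; `truth` rows are duplicated to match and a
#'   `block_sizes` element records s_i.
#' @export
apply_ld_duplication <- function(dataset, sampler = block_size_sampler(),
                                 seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  m <- nrow(dataset$study)
  sizes <- if (is.function(sampler)) {
    with_seed(substream_seed(seed, "ld_blocks"), sampler(m))
  } else {
    as.integer(sampler)
  }
  if (length(sizes) != m || any(sizes < 1L)) {
    stop("block sizes must be positive integers, one per SNP", call. = FALSE)
  }
  idx <- rep(seq_len(m), times = sizes)
  study <- dataset$study[idx]
  study$block_id <- idx
  study$snp <- paste0(study$snp, "_", sequence(sizes))
  data.table::setattr(study, "class",
                      c("study_table", class(data.table::data.table())))
  data.table::setattr(study, "m", nrow(study))
  data.table::setattr(study, "d", dataset$config$d)
  out <- list(study = study, truth = dataset$truth[idx],
              pi0_k = dataset$pi0_k, config = dataset$config,
              block_sizes = sizes)
  class(out) <- "sim_dataset"
  out
}

#' Evaluate discovery metrics against simulation truth
#'
#' @param result A data.frame/list with per-SNP `qvalue_f` and `pvalue_f`
#'   (e.g. an `sffdr_fit` result table), aligned with `truth`.
#' @param truth The `truth` table of a `sim_dataset` (column `H`), or a
#'   `sim_dataset`.
#' @param fdr_targets q-value thresholds at which FDP and power are
#'   computed (default 0.01).
#' @param p_thresholds P-value thresholds at which type I error and power
#'   are computed (default `c(1e-4, 5e-8)`).
#' @param pi0_z Optional estimated pi0(z) for RMSE against the true curve.
#' @return A `data.table` with one row per threshold: `metric`
#'   (`"fdr"`/`"pvalue"`), `threshold`, discoveries `R`, false discoveries
#'   `V`, `fdp` (= V / max(R, 1)), `power` (fraction of H = 1 SNPs
#'   discovered), and `type1` (fraction of H = 0 SNPs discovered). The
#'   RMSE of pi0(z), when computable, is attached as attribute
#'   `rmse_pi0`.
#' @export
evaluate_metrics <- function(result, truth, fdr_targets = 0.01,
                             p_thresholds = c(1e-4, 5e-8), pi0_z = NULL) {
  if (inherits(truth, "sim_dataset")) {
    if (is.null(pi0_z)) pi0_z <- result$pi0_z
    truth <- truth$truth
  }
  H <- truth$H
  rows <- list()
  tally <- function(sig, metric, thr) {
    R <- sum(sig); V <- sum(sig & H == 0L)
    data.table::data.table(
      metric = metric, threshold = thr, R = R, V = V,
      fdp = V / max(R, 1L),
      power = if (any(H == 1L)) sum(sig & H == 1L) / sum(H == 1L) else NA_real_,
      type1 = sum(sig & H == 0L) / max(sum(H == 0L), 1L))
  }
  for (t in fdr_targets) {
    rows[[length(rows) + 1L]] <- tally(result$qvalue_f <= t, "fdr", t)
  }
  for (t in p_thresholds) {
    rows[[length(rows) + 1L]] <- tally(result$pvalue_f <= t, "pvalue", t)
  }
  out <- data.table::rbindlist(rows)
  if (!is.null(pi0_z) && "pi0_z_true" %in% names(truth)) {
    data.table::setattr(out, "rmse_pi0",
                        sqrt(mean((pi0_z - truth$pi0_z_true)^2)))
  }
  out[]
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("simulated GWAS dataset: m = %d SNPs, d = %d informative studies\n",
              nrow(x$study), x$config$d))
  cat(sprintf("  primary '%s' (alpha0 = %.1f), informative '%s' (alpha = %g), effect '%s'\n",
              x$config$primary_strength, x$config$alpha0,
              x$config$informative_strength, x$config$alpha_inf,
              x$config$effect_strength))
  cat(sprintf("  non-null SNPs: %d (%.2f%%)\n", sum(x$truth$H),
              100 * mean(x$truth$H)))
  invisible(x)
}
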