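#' Surrogate functional FDR analysis of a harmonized study
#'
#' Runs the full pipeline on a harmonized study table: fit pi0(z) on the
#' training SNPs, build the surrogate variable, estimate the joint density
#' f(p, r) (and, when SNPs in LD are scored, the marginal f(r)), and
#' compute the functional local FDR, functional q value, and functional
#' P value for every SNP.
#'
#' Training SNPs are taken from, in order of precedence: the `training`
#' argument, an `is_training` column, a `block_id` column (one SNP per
#' block via [select_training_snps()]), or — when none are present — all
#' SNPs ("use-all", appropriate when the SNPs are already approximately
#' independent).
#'
#' @param study A `study_table` (see [harmonize_studies()],
#'   [study_table()]).
#' @param training Optional logical vector or `training_selection`.
#' @param selection_mode Passed to [select_training_snps()] when training
#'   SNPs are chosen from blocks (default `"informative"`).
#' @param lambda_grid,knot_quantiles,pi0_floor,min_training Passed to
#'   [fit_pi0()].
#' @param span_floor,density_floor,probit_clamp,grid_size Passed to
#'   [fit_joint_density()].
#' @param lfdr_floor Floor for the functional local FDR (default 1e-12).
#' @param pi0_method Overall-pi0 method, `"mean"` or `"max_qf"`.
#' @param null_robust If `TRUE`, use the constant-pi0 / enlarged-span
#'   stabilization for primary studies with no genetic signal.
#' @param seed Integer seed driving all internal randomness (surrogate
#'   tie-breaking, training sampling).
#' @return An object of class `sffdr_fit`: a list with `results` (a
#'   `data.table` with the input columns plus `lfdr_f`, `qvalue_f`,
#'   `pvalue_f`, `is_training`), `pi0_fit`, `surrogate`, `density`,
#'   `pi0_overall`, `span`, and `seed`.
#' @examples
#' sim <- simulate_independent(sim_config(m = 5000, seed = 7))
#' fit <- sffdr(sim$study, seed = 7)
#' head(fit$results)
#' @export
sffdr <- function(study, training = NULL,
                  selection_mode = c("informative", "random"),
                  lambda_grid = seq(0.05, 0.90, by = 0.05),
                  knot_quantiles = c(0.005, 0.01, 0.025, 0.05, 0.1),
                  pi0_floor = 1e-4, min_training = 1000L,
                  span_floor = 0.02, density_floor = 1e-10,
                  probit_clamp = 1e-15, grid_size = 160L,
                  lfdr_floor = 1e-12,
                  pi0_method = c("mean", "max_qf"),
                  null_robust = FALSE, seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  pi0_method <- match.arg(pi0_method)
  z <- z_matrix(study)
  p <- study$p
  m <- length(p)

  if (inherits(training, "training_selection")) training <- training$is_training
  if (is.null(training)) {
    if ("is_training" %in% names(study) && !anyNA(study$is_training)) {
      training <- study$is_training
    } else if ("block_id" %in% names(study) && !anyNA(study$block_id)) {
      training <- select_training_snps(study, mode = selection_mode,
                                       seed = seed)$is_training
    } else {
      training <- rep(TRUE, m)  # use-all: SNPs treated as independent
    }
  }
  if (length(training) != m) stop("'training' must align with 'study'", call. = FALSE)
  tr <- which(training)
  all_training <- all(training)

  pi0_fit <- fit_pi0(p[tr], z[tr, , drop = FALSE],
                     lambda_grid = lambda_grid,
                     knot_quantiles = knot_quantiles,
                     pi0_floor = pi0_floor, min_training = min_training,
                     null_robust = null_robust)
  pi0_all <- numeric(m)
  pi0_all[tr] <- pi0_fit$pi0_training
  if (!all_training) {
    pi0_all[-tr] <- predict_pi0(pi0_fit, z[-tr, , drop = FALSE])
  }

  surr <- make_surrogate(pi0_all[tr], seed = seed)
  # Training ranks define the density fit (where uniformity of r matters);
  # when LD-dependent SNPs are scored as well, *every* SNP — training
  # included — is evaluated through the monotone quantile map, so SNPs
  # with identical (p, z) always receive identical scores.
  r_all <- if (all_training) {
    surr$r
  } else {
    predict_surrogate(surr, pi0_all)
  }

  pi0_train_mean <- mean(pi0_fit$pi0_training)
  # A constant pi0 fit (explicit null-robust mode, the likelihood-ratio
  # guard, or a too-small training set) means the surrogate carries no
  # information: pair it with the enlarged smoothing span so the density
  # is not overfit along a noise dimension.
  density <- fit_joint_density(p[tr], surr$r,
                               pi0_overall = pi0_train_mean,
                               grid_size = grid_size,
                               span_floor = span_floor,
                               density_floor = density_floor,
                               probit_clamp = probit_clamp,
                               null_robust = null_robust || pi0_fit$constant_fit)
  if (!all_training) {
    density$marginal <- fit_marginal_density(r_all, grid_size = grid_size,
                                             density_floor = density_floor)
  }

  dens <- evaluate_density(density, p, r_all)
  lfdr <- local_fdr(pi0_all, dens$joint, dens$marginal,
                    lfdr_floor = lfdr_floor)
  qf <- qf_values(lfdr)
  pi0_overall <- overall_pi0(pi0_all, method = pi0_method, qf = qf)
  pf <- pf_values(lfdr, qf, pi0_overall)

  results <- data.table::as.data.table(study)
  results$lfdr_f <- lfdr
  results$qvalue_f <- qf
  results$pvalue_f <- pf
  results$is_training <- training
  data.table::setattr(results, "pi0_overall", pi0_overall)

  structure(list(
    results = results,
    pi0_fit = pi0_fit,
    surrogate = surr,
    density = density,
    pi0_z = pi0_all,
    pi0_overall = pi0_overall,
    span = density$span,
    seed = seed),
    class = "sffdr_fit")
}

#' @export
print.sffdr_fit <- function(x, ...) {
  r <- x$results
  cat("surrogate functional FDR fit\n")
  cat(sprintf("  SNPs scored: %d (training: %d)\n", nrow(r), sum(r$is_training)))
  cat(sprintf("  lambda_min = %.2f, span = %.3f, overall pi0 = %.4f\n",
              x$pi0_fit$lambda_min, x$span, x$pi0_overall))
  cat(sprintf("  discoveries: %d at q_f <= 0.01, %d at p_f <= 5e-8\n",
              sum(r$qvalue_f <= 0.01), sum(r$pvalue_f <= 5e-8)))
  invisible(x)
}

#' Run a full sfFDR analysis from files
#'
#' File-level entry point tying the pipeline together: read and harmonize
#' the studies, select training SNPs, fit, and write the per-SNP results
#' TSV, a JSON run summary, and (optionally) fine-mapping output.
#'
#' @param primary Path to the primary summary-statistics file.
#' @param informative Character vector of informative-study file paths.
#' @param blocks Optional path to a two-column TSV (`snp`, `block_id`).
#' @param regions Optional path to a region TSV (`region_id`, `chr`,
#'   `start`, `end`) triggering fine-mapping.
#' @param out_dir Output directory (created if missing).
#' @param column_map Column mapping passed to [read_sumstats()].
#' @param seed Integer seed.
#' @param credible_mass Credible-set mass for fine-mapping (default 0.95).
#' @param ... Further arguments passed to [sffdr()].
#' @return The `sffdr_fit`, invisibly. Side effects: writes
#'   `results.tsv`, `summary.json`, `config.json`, optionally
#'   `finemap.tsv`, into `out_dir`.
#' @export
run_sffdr <- function(primary, informative, blocks = NULL, regions = NULL,
                      out_dir = ".", column_map = c(snp = "snp", chr = "chr",
                                                    pos = "pos", p = "p"),
                      seed = 1L, credible_mass = 0.95, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prim <- read_sumstats(primary, column_map = column_map)
  infs <- lapply(informative, read_sumstats, column_map = column_map)
  blk <- if (!is.null(blocks)) {
    data.table::fread(blocks, header = TRUE)
  } else NULL
  study <- harmonize_studies(prim, infs, blocks = blk)
  fit <- sffdr(study, seed = seed, ...)
  write_results(fit$results, file.path(out_dir, "results.tsv"))

  summ <- list(
    m = nrow(fit$results),
    d = attr(study, "d"),
    n_training = sum(fit$results$is_training),
    lambda_min = fit$pi0_fit$lambda_min,
    span = fit$span,
    pi0_overall = fit$pi0_overall,
    n_pf_5e8 = sum(fit$results$pvalue_f <= 5e-8),
    n_qf_01 = sum(fit$results$qvalue_f <= 0.01),
    n_qf_05 = sum(fit$results$qvalue_f <= 0.05),
    seed = seed)
  write_json_file(summ, file.path(out_dir, "summary.json"))
  write_json_file(list(primary = primary, informative = informative,
                       blocks = blocks, regions = regions, seed = seed),
                  file.path(out_dir, "config.json"))

  if (!is.null(regions)) {
    reg <- data.table::fread(regions, header = TRUE)
    fm <- finemap_regions(fit$results, regions = reg,
                          pi0_overall = fit$pi0_overall,
                          credible_mass = credible_mass)
    write_results(fm, file.path(out_dir, "finemap.tsv"))
  }
  invisible(fit)
}

# Minimal JSON writer for flat named lists (scalars and short vectors),
# keeping the run summary dependency-free.
write_json_file <- function(x, path) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.character(v)) {
      s <- paste0('"', gsub('"', '\\\\"', v), '"')
    } else if (is.logical(v)) {
      s <- ifelse(v, "true", "false")
    } else {
      s <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    }
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ", "), "]")
  }
  body <- paste0('  "', names(x), '": ', vapply(x, enc, character(1)),
                 collapse = ",\n")
  writeLines(paste0("{\n", body, "\n}"), path)
  invisible(path)
}
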