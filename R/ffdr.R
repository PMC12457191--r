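#' Functional local FDR from its components
#'
#' The functional local FDR is the posterior probability that a SNP is
#' null given its P value and the informative data, approximated through
#' the surrogate variable as
#'
#'   Lambda(p, z) = pi0(z) * f(r) / f(p, r)
#'
#' capped at 1 (it is a probability; estimation noise can push the ratio
#' above) and floored to keep downstream Bayes factors finite.
#'
#' @param pi0_z pi0(z) estimates in (0, 1].
#' @param joint Joint density values f(p, r) (>= density floor).
#' @param marginal Marginal density values f(r) (>= density floor);
#'   defaults to 1, the training-set marginal.
#' @param lfdr_floor Lower clip (default 1e-12).
#' @return Numeric vector of local FDRs in `[lfdr_floor, 1]`.
#' @export
local_fdr <- function(pi0_z, joint, marginal = 1, lfdr_floor = 1e-12) {
  clamp(pi0_z * marginal / joint, lfdr_floor, 1)
}

#' Functional q values from functional local FDRs
#'
#' The functional q value of a SNP is the average local FDR over the set
#' of SNPs whose local FDR is less than or equal to its own (ties
#' included) — the estimated positive FDR of the significance region that
#' just admits the SNP. Equivalently, the running mean of the
#' ascending-sorted local FDRs, mapped back to the original order.
#'
#' @param lfdr Functional local FDRs in (0, 1].
#' @return Functional q values, nondecreasing in `lfdr`.
#' @export
qf_values <- function(lfdr) {
  m <- length(lfdr)
  if (m == 0L) stop("empty 'lfdr'", call. = FALSE)
  s <- sort(lfdr)
  run_mean <- cumsum(s) / seq_len(m)
  # weak inequality: each SNP maps to the last sorted position of its value
  run_mean[findInterval(lfdr, s)]
}

#' Functional P values from functional local FDRs
#'
#' The functional P value is the minimum type I error rate at which a SNP
#' is called significant: the empirical CDF of the local FDRs evaluated at
#' the SNP's local FDR, times its functional q value, divided by the
#' overall proportion of truly null tests:
#'
#'   p_f = ECDF(Lambda) * q_f / pi0
#'
#' It behaves like a standard P value but incorporates the informative
#' data. The ECDF uses a weak inequality with denominator equal to the
#' number of scored SNPs.
#'
#' @param lfdr Functional local FDRs in (0, 1].
#' @param qf Functional q values aligned with `lfdr`.
#' @param pi0_overall Overall proportion of truly null tests in (0, 1].
#' @return Functional P values clipped to (0, 1].
#' @export
pf_values <- function(lfdr, qf, pi0_overall) {
  m <- length(lfdr)
  if (m == 0L) stop("empty 'lfdr'", call. = FALSE)
  if (length(qf) != m) stop("'lfdr' and 'qf' must be aligned", call. = FALSE)
  if (!is.finite(pi0_overall) || pi0_overall <= 0) {
    stop("'pi0_overall' must be positive", call. = FALSE)
  }
  ecdf_l <- findInterval(lfdr, sort(lfdr)) / m
  clamp(ecdf_l * qf / pi0_overall, .Machine$double.xmin, 1)
}

#' Overall proportion of truly null tests
#'
#' Either the average of the per-SNP pi0(z) estimates (the primary
#' formula) or the maximum functional q value in the study.
#'
#' @param pi0_z Per-SNP pi0(z) estimates.
#' @param method `"mean"` (default) or `"max_qf"`.
#' @param qf Functional q values, required for `method = "max_qf"`.
#' @return A single probability in (0, 1].
#' @export
overall_pi0 <- function(pi0_z, method = c("mean", "max_qf"), qf = NULL) {
  method <- match.arg(method)
  if (length(pi0_z) == 0L) stop("empty 'pi0_z'", call. = FALSE)
  est <- if (method == "mean") {
    mean(pi0_z)
  } else {
    if (is.null(qf)) stop("method 'max_qf' requires 'qf'", call. = FALSE)
    max(qf)
  }
  clamp(est, .Machine$double.xmin, 1)
}

#' Expected false discoveries at a q-value threshold
#'
#' The expected number of false discoveries in a discovery set equals the
#' number of discoveries times the q value at the threshold: for example
#' 226 discoveries at q_f = 1.75e-3 imply 226 * 1.75e-3 = 0.39 expected
#' false discoveries.
#'
#' @param n_discoveries Number of SNPs declared significant.
#' @param qf_threshold The q value at the significance threshold.
#' @return Expected number of false discoveries.
#' @export
expected_false_discoveries <- function(n_discoveries, qf_threshold) {
  n_discoveries * qf_threshold
}
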