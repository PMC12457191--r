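#' Storey q values (non-functional baseline)
#'
#' Standard q values computed from the primary P values alone, ignoring
#' any informative studies — the comparison baseline for the functional
#' quantities. The null proportion is estimated by Storey's smoother:
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) on the grid
#' lambda = 0.05, 0.10, ..., 0.95, smoothed by a cubic smoothing spline
#' (df = 3) and evaluated at the largest lambda. q values are then
#'
#'   q_i = pi0_hat * min over \{j : p_j >= p_i\} of m p_j / rank(p_j)
#'
#' via the right-to-left running minimum, clipped to (0, 1]. With
#' `pi0_method = "fixed"` and `pi0_fixed = 1` this reduces exactly to
#' Benjamini-Hochberg adjusted P values.
#'
#' @param p P values in (0, 1].
#' @param pi0_method `"smoother"` (default) or `"fixed"`.
#' @param pi0_fixed Null-proportion value used when
#'   `pi0_method = "fixed"`.
#' @param lambda_grid Grid for the smoother
#'   (default `seq(0.05, 0.95, 0.05)`).
#' @return A list of class `qvalue_result` with elements `pi0_hat` and
#'   `qvalues` (aligned with `p`).
#' @export
storey_qvalue <- function(p, pi0_method = c("smoother", "fixed"),
                          pi0_fixed = NULL,
                          lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m == 0L) stop("empty 'p'", call. = FALSE)
  check_prob(p, "p")
  if (pi0_method == "fixed") {
    if (is.null(pi0_fixed)) stop("'pi0_fixed' required for pi0_method = \"fixed\"",
                                 call. = FALSE)
    pi0 <- pi0_fixed
  } else {
    pi0_lambda <- vapply(lambda_grid,
                         function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    pi0 <- clamp(pi0, 1e-8, 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- m * p[o] / (m:1)         # m * p_(j) / rank at descending p
  q_sorted <- pmin(cummin(ro * pi0), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(pi0_hat = pi0, qvalues = q), class = "qvalue_result")
}
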