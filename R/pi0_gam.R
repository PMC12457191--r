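#' Fit the functional proportion of truly null SNPs pi0(z)
#'
#' Estimates pi0(z), the prior probability that a SNP is null given the
#' informative-trait P values z, from the training SNPs. For each value of
#' the thresholding parameter lambda the indicator eta_lambda = 1{p > lambda}
#' is regressed on additive natural cubic splines of each informative trait
#' (logistic link), knots placed at the lower quantiles of each trait where
#' alternative P values concentrate:
#'
#'   logit(E[eta_lambda(z)]) = b0 + sum_k f_k(z_k)
#'
#' and pi0(z; lambda) = E_hat[eta_lambda(z)] / (1 - lambda), which is a
#' conservative (upward-biased) estimator of pi0(z). The lambda minimizing a
#' mean-integrated-squared-error proxy is selected: each fit is scored
#' against the pointwise average of the fits across the whole lambda grid
#' (a variance-reduced consensus), and the grid value with the smallest
#' mean squared difference — the smallest idiosyncratic deviation — wins.
#'
#' @param p Numeric vector of training primary P values in (0, 1].
#' @param z Matrix (n x d) of training informative P values in (0, 1].
#' @param lambda_grid Grid of thresholding parameters
#'   (default `seq(0.05, 0.90, by = 0.05)`).
#' @param knot_quantiles Quantiles of each z_k at which spline knots are
#'   placed (default `c(0.005, 0.01, 0.025, 0.05, 0.1)`).
#' @param pi0_floor Lower clip for predicted pi0 (default `1e-4`); values
#'   above 1 (legitimate under the 1/(1-lambda) scaling) are truncated to 1.
#' @param min_training Minimum training size for the GAM (default 1000);
#'   below it the fit falls back to a constant (intercept-only) model.
#' @param null_robust If `TRUE`, the fitted pi0(z) is replaced by its
#'   constant mean — the stabilization recommended when the primary trait
#'   carries no genetic signal, where a flexible fit can overfit noise.
#' A likelihood-ratio guard protects against uninformative covariates: if
#' the additive terms explain no deviance at the selected lambda (LRT
#' against the intercept-only model, threshold 0.01), the fit falls back
#' to a constant pi0 — a flexible curve fitted to pure noise would only
#' destabilize the downstream surrogate.
#'
#' @return An object of class `pi0_fit` with elements `lambda_grid`,
#'   `lambda_min`, `mise_curve`, `coefficients` (per-lambda), `basis`
#'   (per-covariate spline bases), `pi0_training`, `lrt_p` (P value of the
#'   covariate likelihood-ratio test), `constant_fit`, and config echoes.
#' @seealso [predict_pi0()]
#' @export
fit_pi0 <- function(p, z,
                    lambda_grid = seq(0.05, 0.90, by = 0.05),
                    knot_quantiles = c(0.005, 0.01, 0.025, 0.05, 0.1),
                    pi0_floor = 1e-4, min_training = 1000L,
                    null_robust = FALSE) {
  z <- as.matrix(z)
  n <- length(p)
  if (nrow(z) != n) stop("'p' and 'z' must have matching rows", call. = FALSE)
  check_prob(p, "p")
  check_prob(as.numeric(z), "z")
  if (any(lambda_grid <= 0 | lambda_grid >= 1)) {
    stop("'lambda_grid' must lie in (0, 1)", call. = FALSE)
  }
  constant_fit <- n < min_training

  # One spline basis per covariate, reused across the whole lambda grid.
  basis <- vector("list", ncol(z))
  for (k in seq_len(ncol(z))) {
    zk <- z[, k]
    if (constant_fit || diff(range(zk)) < .Machine$double.eps^0.5) {
      basis[[k]] <- NULL  # constant covariate carries no information
    } else {
      knots <- unique(stats::quantile(zk, knot_quantiles, names = FALSE,
                                      type = 7))
      knots <- knots[knots > min(zk) & knots < max(zk)]
      basis[[k]] <- if (length(knots) == 0L) {
        splines::ns(zk, df = 1)
      } else {
        splines::ns(zk, knots = knots)
      }
    }
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  for (k in seq_along(basis)) if (!is.null(basis[[k]])) X <- cbind(X, basis[[k]])

  nl <- length(lambda_grid)
  coefs <- matrix(NA_real_, ncol(X), nl)
  pi0_mat <- matrix(NA_real_, n, nl)
  ok <- logical(nl)
  beta <- NULL
  # Fit from the largest lambda down so each fit warm-starts the next:
  # neighbouring lambdas give nearly identical coefficients.
  for (j in rev(seq_len(nl))) {
    lam <- lambda_grid[j]
    y <- as.numeric(p > lam)
    fit <- tryCatch(irls_logit(X, y, start = beta),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        list(coef = stats::glm.fit(X, y, family = stats::binomial())$coefficients),
        error = function(e) NULL)
    }
    if (is.null(fit) || anyNA(fit$coef)) {
      warning(sprintf("pi0 GAM did not converge at lambda = %.2f; dropped", lam),
              call. = FALSE)
      next
    }
    beta <- fit$coef
    coefs[, j] <- beta
    pi0_mat[, j] <- clamp(stats::plogis(drop(X %*% beta)) / (1 - lam),
                          pi0_floor, 1)
    ok[j] <- TRUE
  }
  if (!any(ok)) stop("pi0 GAM failed at every lambda", call. = FALSE)

  # MISE proxy: the pointwise mean of the fits across the whole lambda grid
  # is a variance-reduced consensus estimate of pi0(z) (the thresholding
  # bias is small relative to the per-lambda fitting noise everywhere except
  # the grid edges, and averaging cancels the idiosyncratic noise); the
  # selected lambda minimizes the mean squared distance to this consensus,
  # i.e. has the smallest idiosyncratic deviation.
  ref <- rowMeans(pi0_mat[, ok, drop = FALSE])
  mise <- rep(NA_real_, nl)
  mise[ok] <- colMeans((pi0_mat[, ok, drop = FALSE] - ref)^2)
  j_min <- which.min(mise)

  # Guard against fitting pure noise: if the additive terms explain no
  # deviance in the selected-lambda model (likelihood-ratio test against
  # the intercept), the covariates carry no usable information and a
  # flexible pi0(z) would only overfit — fall back to the constant fit
  # (the same stabilization as null-robust mode, applied adaptively).
  lrt_p <- NA_real_
  if (!constant_fit && ncol(X) > 1L) {
    y_min <- as.numeric(p > lambda_grid[j_min])
    mu_full <- clamp(stats::plogis(drop(X %*% coefs[, j_min])), 1e-12, 1 - 1e-12)
    dev_full <- -2 * sum(y_min * log(mu_full) + (1 - y_min) * log(1 - mu_full))
    mu0 <- clamp(mean(y_min), 1e-12, 1 - 1e-12)
    dev_null <- -2 * sum(y_min * log(mu0) + (1 - y_min) * log(1 - mu0))
    lrt_p <- stats::pchisq(dev_null - dev_full, df = ncol(X) - 1L,
                           lower.tail = FALSE)
    if (!is.finite(lrt_p) || lrt_p >= 0.01) constant_fit <- TRUE
  }

  pi0_train <- pi0_mat[, j_min]
  if (null_robust || constant_fit) pi0_train <- rep(mean(pi0_train), n)

  structure(list(
    lambda_grid = lambda_grid,
    lambda_min = lambda_grid[j_min],
    mise_curve = mise,
    coefficients = coefs[, j_min],
    coefficients_all = coefs,
    basis = basis,
    knot_quantiles = knot_quantiles,
    pi0_floor = pi0_floor,
    null_robust = null_robust,
    constant_fit = constant_fit,
    lrt_p = lrt_p,
    pi0_training = pi0_train,
    d = ncol(z), n = n),
    class = "pi0_fit")
}

#' Predict pi0(z) for new SNPs
#'
#' Evaluates the selected-lambda GAM at new informative P values, applies
#' the 1/(1 - lambda_min) scaling, and clips into `[pi0_floor, 1]`.
#' Evaluating at the training covariates reproduces `pi0_training`.
#'
#' @param fit A `pi0_fit` from [fit_pi0()].
#' @param z Matrix (n x d) of informative P values in (0, 1].
#' @return Numeric vector of pi0 estimates in `[pi0_floor, 1]`.
#' @export
predict_pi0 <- function(fit, z) {
  stopifnot(inherits(fit, "pi0_fit"))
  z <- as.matrix(z)
  if (ncol(z) != fit$d) {
    stop(sprintf("'z' has %d columns; fit expects d = %d", ncol(z), fit$d),
         call. = FALSE)
  }
  check_prob(as.numeric(z), "z")
  if (fit$null_robust || fit$constant_fit) {
    return(rep(fit$pi0_training[1L], nrow(z)))
  }
  X <- cbind(rep(1, nrow(z)))
  for (k in seq_len(fit$d)) {
    if (!is.null(fit$basis[[k]])) {
      X <- cbind(X, stats::predict(fit$basis[[k]], z[, k]))
    }
  }
  clamp(stats::plogis(drop(X %*% fit$coefficients)) / (1 - fit$lambda_min),
        fit$pi0_floor, 1)
}

#' @export
print.pi0_fit <- function(x, ...) {
  cat("pi0(z) GAM fit\n")
  cat(sprintf("  training SNPs: %d, informative traits: %d\n", x$n, x$d))
  cat(sprintf("  lambda grid: %d values, lambda_min = %.2f\n",
              length(x$lambda_grid), x$lambda_min))
  cat(sprintf("  mean pi0(z): %.4f (range %.4f - %.4f)\n",
              mean(x$pi0_training), min(x$pi0_training), max(x$pi0_training)))
  if (x$null_robust) cat("  null-robust mode: constant pi0\n")
  if (x$constant_fit) cat("  constant fallback (training below minimum size)\n")
  invisible(x)
}

# Newton/IRLS for logistic regression with a fixed design. Uses symmetric
# crossprod and warm starts; errors if it fails so the caller can fall back
# to stats::glm.fit. Convergence on the Newton-step norm (equivalent to the
# deviance criterion near the optimum, but cheaper to evaluate).
irls_logit <- function(X, y, start = NULL, maxit = 30L, tol = 1e-6) {
  p_ncol <- ncol(X)
  beta <- if (is.null(start) || length(start) != p_ncol || anyNA(start)) {
    c(stats::qlogis(clamp(mean(y), 1e-6, 1 - 1e-6)), rep(0, p_ncol - 1L))
  } else {
    start
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * sqrt(w)) + diag(1e-10, p_ncol)
    g <- crossprod(X, y - mu)
    step <- tryCatch(drop(solve(H, g)),
                     error = function(e) stop("IRLS solve failed", call. = FALSE))
    if (anyNA(step) || any(!is.finite(step))) {
      stop("IRLS produced non-finite coefficients", call. = FALSE)
    }
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, iter = it)
}
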