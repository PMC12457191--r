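#' Build the surrogate variable from estimated pi0(z)
#'
#' The surrogate variable r is the uniform quantile transformation of the
#' estimated pi0(z): ascending ranks divided by the training size, with
#' ties broken by a seeded random permutation. Conditioning the primary
#' P value on the one-dimensional r instead of the d-dimensional z makes
#' nonparametric density estimation tractable; on the training set r is by
#' construction a permutation of {1/m, 2/m, ..., 1} so f(r) = 1.
#'
#' @param pi0_values Numeric vector of estimated pi0(z) values in `[0, 1]`.
#' @param seed Integer seed for the tie-breaking permutation.
#' @return An object of class `surrogate_map` with elements `r` (the
#'   training surrogate values), `quantile_map` (a monotone interpolator
#'   from pi0 to r used to place left-out SNPs on the r scale), and `seed`.
#' @export
make_surrogate <- function(pi0_values, seed = 1L) {
  m <- length(pi0_values)
  if (m == 0L) stop("empty 'pi0_values'", call. = FALSE)
  if (any(!is.finite(pi0_values) | pi0_values < 0 | pi0_values > 1)) {
    stop("'pi0_values' must be finite probabilities in [0, 1]", call. = FALSE)
  }
  r <- with_seed(substream_seed(seed, "surrogate_ties"),
                 rank(pi0_values, ties.method = "random")) / m
  # Monotone map pi0 -> r for out-of-training prediction; tied pi0 values
  # collapse to their mean rank so the map is a function. A degenerate
  # training set (constant pi0, e.g. null-robust mode) maps everything to
  # the mean rank.
  if (length(unique(pi0_values)) >= 2L) {
    o <- order(pi0_values, r)
    qmap <- stats::approxfun(pi0_values[o], r[o], rule = 2, ties = mean)
  } else {
    mean_r <- mean(r)
    qmap <- function(x) rep(mean_r, length(x))
  }
  structure(list(r = r, quantile_map = qmap, seed = seed, m = m),
            class = "surrogate_map")
}

#' Predict surrogate values for left-out SNPs
#'
#' @param map A `surrogate_map` from [make_surrogate()].
#' @param pi0_values pi0(z) estimates of the left-out SNPs.
#' @return Surrogate values in (0, 1], by monotone interpolation of the
#'   training empirical quantile function.
#' @export
predict_surrogate <- function(map, pi0_values) {
  stopifnot(inherits(map, "surrogate_map"))
  map$quantile_map(pi0_values)
}

#' Estimate the joint density f(p, r) on the probit scale
#'
#' Local-likelihood kernel density estimate of the joint distribution of
#' the primary P value and the surrogate variable. P values are mapped to
#' the probit scale x = qnorm(p) where the null component is standard
#' normal and signal appears as a left-tail excess; the density of (x, r)
#' is estimated by a binned local quadratic Poisson (log-density) smoother
#' with a nearest-neighbour span, and mapped back to the original P scale
#' by the change of variables f(p, r) = f(x, r) / dnorm(x).
#'
#' The nearest-neighbour span — the fraction of the data covered by each
#' smoothing neighbourhood — is the estimated proportion of truly
#' alternative tests, `1 - pi0_overall`, floored at `span_floor` (0.02):
#' sparse signal needs a tight neighbourhood to resolve the non-null tail.
#' Fitting the local log-density as a quadratic keeps the estimator
#' well-behaved in the extreme left tail (genome-wide-significant P
#' values), where an ordinary kernel estimator would collapse to zero.
#'
#' @param p Primary P values in (0, 1].
#' @param r Surrogate values in (0, 1] (same length as `p`).
#' @param pi0_overall Estimated overall proportion of truly null tests;
#'   sets the span as `max(1 - pi0_overall, span_floor)`.
#' @param span Optional explicit span in (0, 1], overriding `pi0_overall`.
#' @param grid_size Number of nodes per axis of the stored evaluation grid
#'   (default 160).
#' @param span_floor Minimum span (default 0.02).
#' @param density_floor Lower clip for stored densities (default 1e-10),
#'   keeping downstream local FDRs finite.
#' @param probit_clamp P values are clamped to
#'   `[probit_clamp, 1 - probit_clamp]` (default 1e-15) before the probit
#'   transform, keeping qnorm finite without distorting
#'   genome-wide-significant P values (~5e-8).
#' @param null_robust If `TRUE` the span is additionally floored at 0.1,
#'   the stabilization used when the primary study has no signal.
#' @param min_points Minimum number of observations (default 200).
#' @return An object of class `density_fit` with elements `grid_p`
#'   (probit-scale node coordinates), `grid_r`, `joint_values`
#'   (original-P-scale densities, `grid_size` x `grid_size`, floored),
#'   `log_joint_x` (probit-scale log densities, used for interpolation),
#'   `span`, and the configuration used. The marginal density of r is
#'   attached by [fit_marginal_density()] when SNPs in LD are scored;
#'   without it the training marginal f(r) = 1 is used.
#' @export
fit_joint_density <- function(p, r, pi0_overall = NULL, span = NULL,
                              grid_size = 160L, span_floor = 0.02,
                              density_floor = 1e-10, probit_clamp = 1e-15,
                              null_robust = FALSE, min_points = 200L) {
  n <- length(p)
  if (n != length(r)) stop("'p' and 'r' must have equal length", call. = FALSE)
  if (n < min_points) {
    stop(sprintf("joint density needs at least %d points (got %d)",
                 min_points, n), call. = FALSE)
  }
  check_prob(p, "p")
  if (any(!is.finite(r) | r <= 0 | r > 1)) {
    stop("'r' must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(span)) {
    if (is.null(pi0_overall)) stop("supply 'pi0_overall' or 'span'", call. = FALSE)
    span <- max(1 - pi0_overall, span_floor)
  }
  if (null_robust) span <- max(span, 0.1)
  if (!is.finite(span) || span <= 0 || span > 1) {
    stop("'span' must lie in (0, 1]", call. = FALSE)
  }

  x <- stats::qnorm(clamp(p, probit_clamp, 1 - probit_clamp))
  x_lo <- min(x) - 0.5
  x_hi <- max(x) + 0.5

  # --- bin the data ------------------------------------------------------
  nxb <- 192L; nrb <- 64L
  bx_breaks <- seq(x_lo, x_hi, length.out = nxb + 1L)
  br_breaks <- seq(0, 1, length.out = nrb + 1L)
  bx <- (bx_breaks[-1L] + bx_breaks[-(nxb + 1L)]) / 2
  br <- (br_breaks[-1L] + br_breaks[-(nrb + 1L)]) / 2
  ix <- clamp(findInterval(x, bx_breaks, rightmost.closed = TRUE), 1L, nxb)
  ir <- clamp(findInterval(r, br_breaks, rightmost.closed = TRUE), 1L, nrb)
  cnt <- tabulate((ir - 1L) * nxb + ix, nbins = nxb * nrb)
  area <- diff(bx_breaks[1:2]) * diff(br_breaks[1:2])
  occ <- which(cnt > 0L)
  cnt_occ <- cnt[occ]
  bx_all <- rep(bx, times = nrb)
  br_all <- rep(br, each = nxb)

  sx <- stats::sd(x); if (!is.finite(sx) || sx == 0) sx <- 1
  sr <- stats::sd(r); if (!is.finite(sr) || sr == 0) sr <- 1
  k_nn <- ceiling(span * n)

  # --- local quadratic Poisson fit at each node of a coarse grid ---------
  nxf <- 48L; nrf <- 25L
  fx <- seq(x_lo, x_hi, length.out = nxf)
  fr <- seq(0, 1, length.out = nrf)
  logf <- matrix(NA_real_, nxf, nrf)
  min_h2 <- (2.5 * diff(bx_breaks[1:2]) / sx)^2 + (2.5 * diff(br_breaks[1:2]) / sr)^2

  for (jr in seq_len(nrf)) {
    dr2_all <- ((br_all - fr[jr]) / sr)^2
    dr2_occ <- dr2_all[occ]
    for (jx in seq_len(nxf)) {
      dx2_occ <- ((bx_all[occ] - fx[jx]) / sx)^2
      d2_occ <- dx2_occ + dr2_occ
      o <- order(d2_occ)
      cs <- cumsum(cnt_occ[o])
      h2 <- d2_occ[o[min(which(cs >= k_nn)[1L], length(o), na.rm = TRUE)]]
      if (!is.finite(h2)) h2 <- max(d2_occ)
      h2 <- max(h2, min_h2)
      dx2_all <- ((bx_all - fx[jx]) / sx)^2
      d2_all <- dx2_all + dr2_all
      sel <- which(d2_all < h2)
      w <- (1 - (d2_all[sel] / h2)^1.5)^3  # radial tricube
      logf[jx, jr] <- local_pois_quad(
        cnt[sel], w,
        (bx_all[sel] - fx[jx]) / (sqrt(h2) * sx),
        (br_all[sel] - fr[jr]) / (sqrt(h2) * sr),
        log(n * area), density_floor)
    }
  }

  # Three passes of a 3x3 binomial filter damp node-level noise; the fit
  # grid is much finer than the smoothing neighbourhoods so the extra bias
  # is negligible relative to the kernel bias.
  for (pass_i in 1:3) logf <- smooth_surface(logf)

  # Normalize on the probit-scale rectangle so the density integrates to 1.
  fz <- exp(logf)
  zx <- apply(fz, 2, function(col) trapz(fx, col))
  logf <- logf - log(trapz(fr, zx))

  # --- resample onto the stored evaluation grid --------------------------
  grid_p <- seq(x_lo, x_hi, length.out = grid_size)
  grid_r <- seq(0, 1, length.out = grid_size)
  eg <- expand.grid(xq = grid_p, rq = grid_r)
  log_joint_x <- matrix(interp_bilinear(fx, fr, logf, eg$xq, eg$rq),
                        grid_size, grid_size)
  joint_values <- exp(log_joint_x) / stats::dnorm(grid_p)
  joint_values <- pmax(joint_values, density_floor)

  structure(list(
    grid_p = grid_p, grid_r = grid_r,
    joint_values = joint_values,
    log_joint_p = log(joint_values),
    span = span, density_floor = density_floor,
    probit_clamp = probit_clamp, n = n,
    marginal = NULL),
    class = "density_fit")
}

# Local quadratic Poisson log-density fit at one node. `cnt` are bin
# counts, `w` kernel weights, (ux, ur) bin offsets scaled by the bandwidth,
# `off` = log(n * bin_area). Returns the log density at the node.
local_pois_quad <- function(cnt, w, ux, ur, off, density_floor) {
  tot <- sum(w * cnt)
  if (tot <= 0) return(log(density_floor))
  X <- cbind(1, ux, ur, ux^2, ux * ur, ur^2)
  # start from the weighted mean density over the neighbourhood
  eta0 <- log(tot / sum(w)) - off
  beta <- c(eta0, rep(0, 5L))
  for (it in 1:12) {
    eta <- off + drop(X %*% beta)
    eta <- pmin(eta, off + 20)  # guard against overflow mid-iteration
    mu <- exp(eta)
    Wd <- w * mu
    grad <- drop(crossprod(X, w * (cnt - mu)))
    H <- crossprod(X * sqrt(Wd)) + diag(1e-8, 6L)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # dampen very large steps (rare, deep-tail nodes)
    sc <- max(1, max(abs(step)) / 4)
    beta <- beta + step / sc
    if (max(abs(step)) < 1e-8) break
  }
  if (!is.finite(beta[1L])) return(log(density_floor))
  max(beta[1L], log(density_floor))
}

# 3x3 binomial filter with edge replication.
smooth_surface <- function(m) {
  pad <- rbind(m[1L, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  kern <- outer(c(1, 2, 1), c(1, 2, 1)) / 16
  for (i in 1:3) for (j in 1:3) {
    out <- out + kern[i, j] * pad[i:(i + nr - 1L), j:(j + nc - 1L)]
  }
  out
}

#' Estimate the marginal density f(r) of the surrogate variable
#'
#' When SNPs in LD are scored, the surrogate values of the full SNP set
#' are generally not uniform (blocks sharing small pi0(z) pile up mass at
#' small r), so the marginal enters the local FDR as f(r)/f(p, r). The
#' marginal is estimated by a boundary-corrected (reflection) Gaussian
#' kernel density on `[0, 1]`, normalized to integrate to 1 and floored.
#'
#' @param r_all Surrogate values of all scored SNPs, in (0, 1].
#' @param grid_size Number of evaluation nodes on `[0, 1]` (default 160).
#' @param density_floor Lower clip (default 1e-10).
#' @param bw Optional kernel bandwidth; defaults to `bw.nrd0`.
#' @return An object of class `marginal_density` with elements `grid_r`,
#'   `values`, and `bw`.
#' @export
fit_marginal_density <- function(r_all, grid_size = 160L,
                                 density_floor = 1e-10, bw = NULL) {
  n <- length(r_all)
  if (n == 0L) stop("empty 'r_all'", call. = FALSE)
  if (any(!is.finite(r_all) | r_all <= 0 | r_all > 1)) {
    stop("'r_all' must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(bw)) {
    bw <- stats::bw.nrd0(r_all)
    if (!is.finite(bw) || bw <= 0) bw <- 0.05
  }
  aug <- c(-r_all, r_all, 2 - r_all)
  de <- stats::density(aug, bw = bw, from = 0, to = 1, n = grid_size)
  vals <- de$y * 3
  vals <- vals / trapz(de$x, vals)
  vals <- pmax(vals, density_floor)
  structure(list(grid_r = de$x, values = vals, bw = bw, n = n),
            class = "marginal_density")
}

#' Evaluate fitted joint and marginal densities at query points
#'
#' Interpolates the stored log densities (bilinear over the probit-scale
#' grid for the joint, linear for the marginal); a query at a grid node
#' returns the stored value exactly, and queries outside the grid clamp to
#' the nearest edge value. Outputs are floored at the density floor.
#'
#' @param fit A `density_fit` from [fit_joint_density()].
#' @param p Query P values in (0, 1].
#' @param r Query surrogate values in (0, 1].
#' @param marginal Optional `marginal_density`; when absent (independent
#'   training SNPs) the marginal is the uniform density 1.
#' @return A list with numeric vectors `joint` and `marginal`.
#' @export
evaluate_density <- function(fit, p, r, marginal = fit$marginal) {
  stopifnot(inherits(fit, "density_fit"))
  x <- stats::qnorm(clamp(p, fit$probit_clamp, 1 - fit$probit_clamp))
  lj <- interp_bilinear(fit$grid_p, fit$grid_r, fit$log_joint_p, x, r)
  joint <- pmax(exp(lj), fit$density_floor)
  marg <- if (is.null(marginal)) {
    rep(1, length(p))
  } else {
    pmax(interp_linear(marginal$grid_r, marginal$values, r),
         fit$density_floor)
  }
  list(joint = joint, marginal = marg)
}

#' Numerically integrate a fitted joint density
#'
#' Quadrature check that the stored density integrates to 1: integrates
#' the P-scale joint values over the probit-coordinate grid with the
#' appropriate Jacobian.
#'
#' @param fit A `density_fit`.
#' @return The integral of f(p, r) dp dr over the stored grid.
#' @export
integrate_density <- function(fit) {
  stopifnot(inherits(fit, "density_fit"))
  fx <- fit$joint_values * stats::dnorm(fit$grid_p)  # back to probit scale
  per_r <- apply(fx, 2, function(col) trapz(fit$grid_p, col))
  trapz(fit$grid_r, per_r)
}

#' @export
print.density_fit <- function(x, ...) {
  cat("probit-scale local-likelihood joint density f(p, r)\n")
  cat(sprintf("  n = %d, span = %.3f, grid %d x %d\n",
              x$n, x$span, length(x$grid_p), length(x$grid_r)))
  cat(sprintf("  integral check: %.4f\n", integrate_density(x)))
  invisible(x)
}
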