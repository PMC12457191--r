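test_that("surrogate is the seeded uniform quantile transform of pi0", {
  s <- make_surrogate(c(0.98, 0.50, 0.75), seed = 1)
  expect_equal(s$r, c(1, 1 / 3, 2 / 3))

  # ties broken by a seeded permutation, reproducibly
  t1 <- make_surrogate(c(0.9, 0.9), seed = 4)
  t2 <- make_surrogate(c(0.9, 0.9), seed = 4)
  expect_identical(t1$r, t2$r)
  expect_setequal(t1$r, c(0.5, 1))

  # output multiset is exactly {1/m, ..., 1} even with heavy ties
  set.seed(2)
  vals <- sample(c(0.7, 0.9, 1), 200, replace = TRUE)
  s3 <- make_surrogate(vals, seed = 9)
  expect_equal(sort(s3$r), (1:200) / 200)

  expect_error(make_surrogate(numeric(0)), "empty")
})

test_that("surrogate prediction interpolates the training quantile map", {
  set.seed(3)
  pi0 <- runif(500, 0.5, 1)
  s <- make_surrogate(pi0, seed = 1)
  # training values map back to their own ranks
  expect_equal(predict_surrogate(s, pi0), s$r, tolerance = 1e-10)
  # predictions are monotone and clamped into (0, 1]
  grid <- seq(0, 1.2, by = 0.05)
  pred <- predict_surrogate(s, grid)
  expect_true(all(diff(pred) >= 0))
  expect_true(all(pred >= 1 / 500 & pred <= 1))
})

test_that("flat-density null: f(p, r) is near 1 with a uniform sample", {
  set.seed(9)
  p <- runif(10000); r <- runif(10000)
  fit <- fit_joint_density(p, r, pi0_overall = 1)
  expect_equal(fit$span, 0.02)  # 1 - pi0 below the floor engages the floor
  sel_p <- pnorm(fit$grid_p) >= 0.05 & pnorm(fit$grid_p) <= 0.95
  sel_r <- fit$grid_r >= 0.05 & fit$grid_r <= 0.95
  expect_lt(max(abs(fit$joint_values[sel_p, sel_r] - 1)), 0.25)
  expect_lt(abs(integrate_density(fit) - 1), 0.02)
})

test_that("probit pipeline recovers a known Beta density (Jacobian check)", {
  set.seed(5)
  m <- 10000
  p <- pmin(pmax(rbeta(m, 2, 5), 1e-12), 1 - 1e-12)
  fit <- fit_joint_density(p, runif(m), span = 0.1)
  pg <- seq(0.005, 0.995, by = 0.005)
  est <- vapply(pg, function(pp) {
    mean(evaluate_density(fit, rep(pp, 50), seq(0.01, 0.99, length.out = 50))$joint)
  }, numeric(1))
  iae <- sum(abs(est - dbeta(pg, 2, 5)) * 0.005)
  expect_lt(iae, 0.1)
})

test_that("joint beats the product of marginals when p depends on r", {
  # p | r mixes in a Beta(0.3, 5) component whose weight grows as r -> 0
  set.seed(12)
  m <- 20000
  r <- runif(m)
  w <- 0.15 * (1 - r)^2
  is_alt <- runif(m) < w
  p <- ifelse(is_alt, rbeta(m, 0.3, 5), runif(m))
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  fit <- fit_joint_density(p, r, span = 0.1)
  truth <- function(pp, rr) {
    ww <- 0.15 * (1 - rr)^2
    (1 - ww) + ww * dbeta(pp, 0.3, 5)
  }
  pg <- seq(0.01, 0.99, by = 0.02)
  rg <- seq(0.025, 0.975, by = 0.05)
  eg <- expand.grid(p = pg, r = rg)
  est_joint <- evaluate_density(fit, eg$p, eg$r)$joint
  # product-of-marginals reference: same estimator fed shuffled r
  fit_ind <- fit_joint_density(p, sample(r), span = 0.1)
  est_prod <- evaluate_density(fit_ind, eg$p, eg$r)$joint
  tru <- truth(eg$p, eg$r)
  ise_joint <- mean((est_joint - tru)^2)
  ise_prod <- mean((est_prod - tru)^2)
  expect_lt(ise_joint, ise_prod)
})

test_that("marginal density is boundary-corrected, normalized and floored", {
  set.seed(4)
  r <- runif(5000)
  fm <- fit_marginal_density(r)
  sel <- fm$grid_r >= 0.05 & fm$grid_r <= 0.95
  expect_lt(max(abs(fm$values[sel] - 1)), 0.1)
  integral <- sum(diff(fm$grid_r) * (fm$values[-1] + fm$values[-length(fm$values)])) / 2
  expect_lt(abs(integral - 1), 0.02)

  # duplicated small-r SNPs shift mass: f(r < 0.2) must exceed f(r > 0.8)
  r_ld <- c(r, rep(r[r < 0.2], 2L))
  fm2 <- fit_marginal_density(r_ld)
  expect_gt(mean(fm2$values[fm2$grid_r < 0.2]),
            mean(fm2$values[fm2$grid_r > 0.8]))

  expect_error(fit_marginal_density(numeric(0)), "empty")
  expect_error(fit_marginal_density(c(0.5, 1.2)), "0, 1")
})

test_that("evaluation is exact at grid nodes, clamped outside, floored", {
  set.seed(6)
  p <- runif(2000); r <- runif(2000)
  fit <- fit_joint_density(p, r, pi0_overall = 0.9)
  fit$marginal <- fit_marginal_density(r)
  i <- 40L; j <- 77L
  at_node <- evaluate_density(fit, pnorm(fit$grid_p[i]), fit$grid_r[j])
  expect_equal(at_node$joint, fit$joint_values[i, j], tolerance = 1e-9)
  # beyond the grid: clamps to the nearest edge value
  lo <- evaluate_density(fit, 1e-300, 0.5)
  edge <- evaluate_density(fit, pnorm(fit$grid_p[1]), 0.5)
  expect_equal(lo$joint, edge$joint)
  out <- evaluate_density(fit, c(1e-14, 0.5, 1), c(1e-9, 0.5, 1))
  expect_true(all(out$joint >= fit$density_floor))
  expect_true(all(out$marginal >= fit$density_floor))
})

test_that("density fitting is deterministic given identical inputs", {
  set.seed(10)
  p <- runif(3000); r <- runif(3000)
  f1 <- fit_joint_density(p, r, pi0_overall = 0.95)
  f2 <- fit_joint_density(p, r, pi0_overall = 0.95)
  expect_identical(f1$joint_values, f2$joint_values)
})

test_that("span contract: floor engages and invalid spans error", {
  set.seed(11)
  p <- runif(1000); r <- runif(1000)
  expect_equal(fit_joint_density(p, r, pi0_overall = 0.99)$span, 0.02)
  expect_equal(fit_joint_density(p, r, pi0_overall = 0.9)$span, 0.1,
               tolerance = 1e-12)
  expect_error(fit_joint_density(p, r, span = 0), "span")
  expect_error(fit_joint_density(p, r, span = 1.5), "span")
  expect_error(fit_joint_density(runif(50), runif(50), span = 0.5),
               "at least")
  # null-robust mode enlarges the span to at least 0.1
  expect_equal(fit_joint_density(p, r, pi0_overall = 1, null_robust = TRUE)$span,
               0.1)
})
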