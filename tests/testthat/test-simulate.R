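test_that("generator honours the stated parameter maps and invariants", {
  cfg <- sim_config(m = 20000L, seed = 2,
                    primary_strength = "high",
                    informative_strength = "high",
                    effect_strength = "large")
  expect_equal(cfg$alpha0, 0.3)
  expect_equal(cfg$alpha_inf, 2)
  expect_equal(cfg$a, 0.6)
  expect_equal(cfg$c, 0.15)
  sim <- simulate_independent(cfg)
  # per-study null proportions live in [1 - gamma, 1 - gamma/2]
  expect_true(all(sim$pi0_k >= 0.975 & sim$pi0_k <= 0.9875))
  # SNPs null in every informative study sit exactly at the baseline prior
  all_null <- rowSums(as.matrix(sim$truth[, c("H_k_1", "H_k_2", "H_k_3")])) == 0
  expect_true(all(sim$truth$pi0_z_true[all_null] == 0.98))
  # generator consistency: E[H] matches mean(1 - pi0(z)) within MC noise
  expected <- mean(1 - sim$truth$pi0_z_true)
  se <- sqrt(expected * (1 - expected) / nrow(sim$study))
  expect_lt(abs(mean(sim$truth$H) - expected), 3 * se)
})

test_that("effect 'none' removes all informative structure", {
  sim <- simulate_independent(sim_config(m = 5000L, effect_strength = "none",
                                         seed = 3))
  expect_true(all(sim$truth$pi0_z_true == 0.98))
  expect_true(all(sim$truth$alpha_z_true == 0.4))
})

test_that("generator is bit-identical under a fixed seed", {
  a <- simulate_independent(sim_config(m = 2000L, seed = 10))
  b <- simulate_independent(sim_config(m = 2000L, seed = 10))
  expect_identical(a$study$p, b$study$p)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- simulate_independent(sim_config(m = 2000L, seed = 11))
  expect_false(identical(a$study$p, c2$study$p))
})

test_that("null informative P values are uniform (KS at level 0.001)", {
  sim <- cached("sim_ks", simulate_independent(sim_config(seed = 13)))
  for (k in 1:3) {
    znull <- sim$study[[paste0("z_", k)]][sim$truth[[paste0("H_k_", k)]] == 0L]
    ks <- suppressWarnings(stats::ks.test(znull, "punif"))  # runif ties are RNG-resolution artifacts
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("stronger informative effects shift alpha(z) downward", {
  mean_alpha <- function(effect) {
    sim <- simulate_independent(sim_config(m = 50000L, seed = 4,
                                           effect_strength = effect))
    overlap <- rowSums(as.matrix(sim$truth[, c("H_k_1", "H_k_2", "H_k_3")])) > 0
    mean(sim$truth$alpha_z_true[overlap & sim$truth$H == 1L])
  }
  a_large <- mean_alpha("large")
  a_mod <- mean_alpha("moderate")
  expect_lt(a_large, a_mod)
  expect_lt(a_mod, 0.4)
})

test_that("oracle local FDR is the exact generative posterior", {
  sim <- simulate_independent(sim_config(m = 3000L, seed = 6))
  lam <- oracle_local_fdr(sim)
  pi0 <- sim$truth$pi0_z_true
  f1 <- dbeta(sim$study$p, sim$truth$alpha_z_true, 5)
  expect_equal(lam, pmin(pi0 / (pi0 + (1 - pi0) * f1), 1))
  # pure-null SNP with flat alternative density: arithmetic check
  expect_equal(unname(pmin(0.98 / (0.98 + 0.02 * 1), 1)), 0.98)
})

test_that("oracle q_f controls the FDR across replicates", {
  fdps <- vapply(1:25, function(i) {
    sim <- simulate_independent(sim_config(m = 20000L, seed = 600 + i))
    qf <- qf_values(oracle_local_fdr(sim))
    sig <- qf <= 0.01
    sum(sig & sim$truth$H == 0L) / max(sum(sig), 1L)
  }, numeric(1))
  expect_lte(mean(fdps), 0.01 + 2 * sd(fdps) / sqrt(length(fdps)))
})

test_that("LD duplication replicates rows and records blocks", {
  sim <- simulate_independent(sim_config(m = 3000L, seed = 7))
  dup <- apply_ld_duplication(sim, sampler = c(rep(1L, 2997), 2L, 1L, 3L))
  expect_equal(nrow(dup$study), 3003L)  # 2997 singletons + 2 + 1 + 3
  # rows within a block are identical in p and z
  blk <- dup$study[dup$study$block_id == 2998L]
  expect_equal(nrow(blk), 2L)
  expect_length(unique(blk$p), 1L)
  expect_length(unique(blk$z_1), 1L)
  # all sizes 1 leaves the data unchanged
  same <- apply_ld_duplication(sim, sampler = rep(1L, 3000))
  expect_equal(same$study$p, sim$study$p)
  # sampler draws are seeded and capped
  s <- block_size_sampler(mean_size = 2.4, cap = 50L)
  d1 <- apply_ld_duplication(sim, s, seed = 5)
  d2 <- apply_ld_duplication(sim, s, seed = 5)
  expect_identical(d1$block_sizes, d2$block_sizes)
  expect_true(all(d1$block_sizes >= 1L & d1$block_sizes <= 50L))
})

test_that("metric evaluation implements the FDP and power conventions", {
  truth <- data.table::data.table(H = c(1L, 1L, 0L, 0L, 0L))
  res <- list(qvalue_f = c(0.001, 0.5, 0.005, 0.5, 0.5),
              pvalue_f = c(1e-6, 0.2, 1e-5, 0.9, 0.9))
  met <- evaluate_metrics(res, truth, fdr_targets = 0.01,
                          p_thresholds = 1e-4)
  expect_equal(met$R, c(2L, 2L))
  expect_equal(met$V, c(1L, 1L))
  expect_equal(met$fdp, c(0.5, 0.5))
  expect_equal(met$power, c(0.5, 0.5))
  expect_equal(met$type1, c(1 / 3, 1 / 3))
  # no discoveries: FDP defined as 0 via max(R, 1)
  met0 <- evaluate_metrics(list(qvalue_f = rep(1, 5), pvalue_f = rep(1, 5)),
                           truth, fdr_targets = 0.01, p_thresholds = 1e-4)
  expect_equal(met0$fdp, c(0, 0))
  # a perfect classifier has power 1 and FDP 0
  perfect <- list(qvalue_f = ifelse(truth$H == 1L, 1e-6, 1),
                  pvalue_f = ifelse(truth$H == 1L, 1e-12, 1))
  metp <- evaluate_metrics(perfect, truth, 0.01, 1e-4)
  expect_equal(metp$power, c(1, 1))
  expect_equal(metp$fdp, c(0, 0))
})
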