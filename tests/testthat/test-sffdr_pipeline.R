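test_that("end-to-end fit returns aligned, bounded results", {
  sim <- cached("sim_pipe", simulate_independent(sim_config(m = 20000L, seed = 31)))
  fit <- cached("fit_pipe", sffdr(sim$study, seed = 31))
  r <- fit$results
  expect_equal(nrow(r), 20000L)
  for (col in c("lfdr_f", "qvalue_f", "pvalue_f")) {
    expect_true(all(r[[col]] > 0 & r[[col]] <= 1))
  }
  # q_f and p_f are nondecreasing in the local FDR
  o <- order(r$lfdr_f)
  expect_true(all(diff(r$qvalue_f[o]) >= -1e-15))
  expect_true(all(diff(r$pvalue_f[o]) >= -1e-15))
  # functional q values find at least as much as they claim: mean local
  # FDR over any rejection set is below the threshold defining it
  sig <- r$qvalue_f <= 0.05
  if (any(sig)) expect_lte(mean(r$lfdr_f[sig]), 0.05 + 1e-12)
})

test_that("refitting with the same seed is bit-identical", {
  sim <- cached("sim_pipe", simulate_independent(sim_config(m = 20000L, seed = 31)))
  f1 <- cached("fit_pipe", sffdr(sim$study, seed = 31))
  f2 <- sffdr(sim$study, seed = 31)
  expect_identical(f1$results$lfdr_f, f2$results$lfdr_f)
  expect_identical(f1$results$pvalue_f, f2$results$pvalue_f)
})

test_that("LD mode trains on one SNP per block and scores every SNP", {
  sim <- simulate_independent(sim_config(m = 8000L, seed = 33))
  dup <- apply_ld_duplication(sim, block_size_sampler(), seed = 33)
  fit <- sffdr(dup$study, seed = 33)
  r <- fit$results
  expect_equal(nrow(r), nrow(dup$study))
  expect_equal(sum(r$is_training), 8000L)   # one per block
  # duplicated SNPs share p and z, hence identical local FDRs
  blk <- r[r$block_id == which.max(dup$block_sizes)]
  expect_length(unique(blk$lfdr_f), 1L)
  # the marginal density of r was fit (non-uniform surrogate support)
  expect_false(is.null(fit$density$marginal))
})

test_that("uninformative traits on null data yield no significant p_f", {
  # permuted-null scenario at reduced scale: no genetic signal anywhere,
  # three uninformative traits, null-robust stabilization on
  set.seed(34)
  m <- 30000L
  st <- study_table(runif(m), cbind(runif(m), runif(m), runif(m)))
  fit <- sffdr(st, null_robust = TRUE, seed = 34)
  expect_equal(sum(fit$results$pvalue_f < 5e-8), 0L)
  expect_gt(fit$pi0_overall, 0.95)
})

test_that("file-based run writes results, summary and finemap outputs", {
  set.seed(35)
  m <- 3000L
  snp <- paste0("rs", 1:m)
  chr <- rep("1", m); pos <- seq_len(m) * 1000L
  sim <- simulate_independent(sim_config(m = m, seed = 35))
  dir <- tempfile(); dir.create(dir)
  prim <- file.path(dir, "primary.tsv")
  data.table::fwrite(data.table::data.table(snp = snp, chr = chr, pos = pos,
                                            p = sim$study$p), prim, sep = "\t")
  infs <- character(3)
  for (k in 1:3) {
    infs[k] <- file.path(dir, paste0("inf", k, ".tsv"))
    data.table::fwrite(data.table::data.table(
      snp = snp, chr = chr, pos = pos, p = sim$study[[paste0("z_", k)]]),
      infs[k], sep = "\t")
  }
  regions <- file.path(dir, "regions.tsv")
  data.table::fwrite(data.table::data.table(
    region_id = "r1", chr = "1", start = 0L, end = 500000L), regions,
    sep = "\t")
  out <- file.path(dir, "out")
  fit <- run_sffdr(prim, infs, regions = regions, out_dir = out, seed = 35)
  expect_true(file.exists(file.path(out, "results.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "finemap.tsv")))
  # summary counts equal recounts from the written table
  res <- data.table::fread(file.path(out, "results.tsv"))
  summ <- readLines(file.path(out, "summary.json"))
  n_qf <- as.integer(sub(".*: *", "", gsub(",", "", grep("n_qf_01", summ, value = TRUE))))
  expect_equal(n_qf, sum(res$qvalue_f <= 0.01))
  # identical config + seed reruns byte-identically
  out2 <- file.path(dir, "out2")
  run_sffdr(prim, infs, regions = regions, out_dir = out2, seed = 35)
  expect_identical(readLines(file.path(out, "results.tsv")),
                   readLines(file.path(out2, "results.tsv")))
})
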