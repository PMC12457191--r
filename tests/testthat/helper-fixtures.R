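# Shared fixtures built in code at test time.

# Write a small sumstats TSV and return its path.
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv"),
                                sep = "\t") {
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  path
}

# A small harmonized study with d = 2 informative traits and LD blocks.
make_toy_study <- function(m = 60L, seed = 42L) {
  set.seed(seed)
  p <- runif(m)
  z <- cbind(runif(m), runif(m))
  study_table(p, z, block_id = rep(seq_len(m / 4L), each = 4L))
}

# Cache heavy objects across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
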