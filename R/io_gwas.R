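#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab or comma separated, optionally gzipped)
#' of per-SNP summary statistics and validates the P-value column. Only the
#' SNP identifier and P value are required; chromosome and base-pair
#' position are carried along when present.
#'
#' @param path Path to a delimited text file with a header row. Gzip
#'   compression is handled transparently.
#' @param column_map Named character vector mapping the roles `snp`, `chr`,
#'   `pos`, `p` to column names in the file. Defaults to columns named
#'   `snp`, `chr`, `pos`, `p`; `chr`/`pos` are optional.
#' @param duplicate_policy `"error"` (default) fails on duplicated SNP
#'   identifiers; `"keep-first"` keeps the first occurrence (real
#'   summary-statistic files often carry multiallelic duplicates).
#' @param clamp_zero If `TRUE`, P values equal to zero are clamped to the
#'   smallest positive double with a warning instead of rejected.
#' @return A `data.table` of class `sumstats_table` with columns
#'   `snp`, `chr`, `pos`, `p`. Rows with missing P are dropped (with a
#'   warning reporting the count); any P outside (0, 1] is an error.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tchr\tpos\tp", "rs1\t1\t100\t0.5", "rs2\t1\t200\t0.01"), tf)
#' read_sumstats(tf)
#' @export
read_sumstats <- function(path,
                          column_map = c(snp = "snp", chr = "chr",
                                         pos = "pos", p = "p"),
                          duplicate_policy = c("error", "keep-first"),
                          clamp_zero = FALSE) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), header = TRUE)
  } else {
    data.table::fread(path, header = TRUE)
  }
  cm <- function(role) {
    if (role %in% names(column_map)) column_map[[role]] else NULL
  }
  for (role in c("snp", "p")) {
    cn <- cm(role)
    if (is.null(cn) || !cn %in% names(dt)) {
      stop(sprintf("configuration error: required column '%s' (role '%s') not found in %s",
                   if (is.null(cn)) role else cn, role, path), call. = FALSE)
    }
  }
  out <- data.table::data.table(
    snp = as.character(dt[[cm("snp")]]),
    chr = if (!is.null(cm("chr")) && cm("chr") %in% names(dt)) {
      as.character(dt[[cm("chr")]])
    } else NA_character_,
    pos = if (!is.null(cm("pos")) && cm("pos") %in% names(dt)) {
      as.integer(dt[[cm("pos")]])
    } else NA_integer_,
    p = suppressWarnings(as.numeric(dt[[cm("p")]]))
  )
  n_missing <- sum(is.na(out$p))
  if (n_missing > 0L) {
    warning(sprintf("%d row%s dropped (missing P value)", n_missing,
                    if (n_missing == 1L) "" else "s"), call. = FALSE)
    out <- out[!is.na(out$p)]
  }
  if (clamp_zero && any(out$p == 0)) {
    warning(sprintf("%d zero P value(s) clamped to %.3g", sum(out$p == 0),
                    .Machine$double.xmin), call. = FALSE)
    out[out$p == 0, "p"] <- .Machine$double.xmin
  }
  bad <- which(out$p <= 0 | out$p > 1)
  if (length(bad) > 0L) {
    stop(sprintf("validation error: P value outside (0,1] at row %d (snp %s, p = %g)",
                 bad[1L], out$snp[bad[1L]], out$p[bad[1L]]), call. = FALSE)
  }
  dup <- duplicated(out$snp)
  if (any(dup)) {
    if (duplicate_policy == "error") {
      stop(sprintf("duplicate snp identifier '%s'; use duplicate_policy = \"keep-first\" to keep the first occurrence",
                   out$snp[which(dup)[1L]]), call. = FALSE)
    }
    out <- out[!dup]
  }
  data.table::setattr(out, "class", c("sumstats_table", class(out)))
  out[]
}

#' Harmonize a primary study with informative studies
#'
#' Intersects the primary and informative tables by SNP identifier
#' (identifier-only matching; alleles and effect directions are not used)
#' and assembles one row per shared SNP with the primary P value and the
#' d informative P values `z_1..z_d`. Rows are ordered by (chr, pos) when
#' both are available for all SNPs, otherwise by primary-file order.
#'
#' @param primary A `sumstats_table` for the primary GWAS.
#' @param informative A list of `sumstats_table` objects (d >= 1).
#' @param blocks Optional `data.frame`/`data.table` with columns `snp` and
#'   `block_id` assigning each SNP to an LD-independent block.
#' @return A `data.table` of class `study_table` with columns `snp`, `chr`,
#'   `pos`, `p`, `z_1..z_d`, and optionally `block_id`. Attributes `m`
#'   (number of SNPs) and `d` (number of informative studies) are set.
#' @export
harmonize_studies <- function(primary, informative, blocks = NULL) {
  if (!is.list(informative) || length(informative) == 0L) {
    stop("'informative' must be a non-empty list of sumstats tables", call. = FALSE)
  }
  if (inherits(informative, "data.frame")) informative <- list(informative)
  d <- length(informative)
  ids <- primary$snp
  for (tab in informative) ids <- intersect(ids, tab$snp)
  if (length(ids) == 0L) stop("no overlapping SNPs between the studies", call. = FALSE)

  out <- data.table::data.table(snp = ids)
  idx <- match(ids, primary$snp)
  out$chr <- primary$chr[idx]
  out$pos <- primary$pos[idx]
  out$p <- primary$p[idx]
  for (k in seq_len(d)) {
    out[[paste0("z_", k)]] <- informative[[k]]$p[match(ids, informative[[k]]$snp)]
  }
  if (!is.null(blocks)) {
    if (!all(c("snp", "block_id") %in% names(blocks))) {
      stop("'blocks' must have columns 'snp' and 'block_id'", call. = FALSE)
    }
    out$block_id <- as.integer(blocks$block_id[match(ids, blocks$snp)])
  }
  if (!anyNA(out$chr) && !anyNA(out$pos)) {
    data.table::setorderv(out, c("chr", "pos"))
  }
  data.table::setattr(out, "class", c("study_table", class(data.table::data.table())))
  data.table::setattr(out, "m", nrow(out))
  data.table::setattr(out, "d", d)
  out[]
}

#' Build a study table directly from vectors
#'
#' Convenience constructor used by the simulation engine and by callers who
#' already hold harmonized P values in memory.
#'
#' @param p Numeric vector of primary-study P values in (0, 1].
#' @param z Matrix (m x d) of informative-study P values in (0, 1].
#' @param snp Optional SNP identifiers (defaults to `snp_1..snp_m`).
#' @param block_id Optional integer LD-block labels.
#' @param is_training Optional logical training flags.
#' @return A `study_table`.
#' @export
study_table <- function(p, z, snp = NULL, block_id = NULL, is_training = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != length(p)) stop("'p' and 'z' must have matching rows", call. = FALSE)
  check_prob(p, "p")
  check_prob(as.numeric(z), "z")
  out <- data.table::data.table(
    snp = if (is.null(snp)) paste0("snp_", seq_along(p)) else as.character(snp),
    chr = NA_character_, pos = NA_integer_, p = as.numeric(p))
  for (k in seq_len(ncol(z))) out[[paste0("z_", k)]] <- z[, k]
  if (!is.null(block_id)) out$block_id <- as.integer(block_id)
  if (!is.null(is_training)) out$is_training <- as.logical(is_training)
  data.table::setattr(out, "class", c("study_table", class(data.table::data.table())))
  data.table::setattr(out, "m", nrow(out))
  data.table::setattr(out, "d", ncol(z))
  out[]
}

# Extract the z matrix (m x d) from a study table.
z_matrix <- function(study) {
  zcols <- grep("^z_[0-9]+$", names(study), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z_", "", zcols)))]
  as.matrix(study[, zcols, with = FALSE])
}

#' Write a results table to TSV
#'
#' Writes the per-SNP results (input columns plus `lfdr_f`, `qvalue_f`,
#' `pvalue_f`, and `is_training` when present) as uncompressed
#' tab-separated text with full double precision, so a write/read
#' round-trip preserves numeric fields.
#'
#' @param results A `data.frame`/`data.table` of per-SNP results.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 999L)
  invisible(path)
}
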