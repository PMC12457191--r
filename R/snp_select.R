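#' Select one training SNP per LD-independent block
#'
#' Chooses a single representative SNP from every LD-independent block to
#' form the training set on which pi0(z) and the joint density are fit.
#' In `"informative"` mode a block whose smallest informative-trait P value
#' falls below `threshold` contributes the SNP attaining that minimum
#' (maximizing coverage of pleiotropic SNPs); all other blocks contribute a
#' uniformly sampled member. In `"random"` mode every block contributes a
#' uniformly sampled member.
#'
#' @param study A `study_table` with a `block_id` column (or an
#'   `is_training` column computed elsewhere).
#' @param mode `"informative"` (default) or `"random"`.
#' @param threshold Informative-trait P-value threshold below which a block
#'   is represented by its most significant informative SNP (default 0.001).
#' @param seed Integer seed driving the uniform draws; reruns with the same
#'   seed are identical.
#' @return A list of class `training_selection` with elements `is_training`
#'   (logical, one per row of `study`), `chosen` (data.table of `block_id`,
#'   `snp`), and `mode`. Ties at the minimum are broken by first occurrence
#'   in table order.
#' @export
select_training_snps <- function(study, mode = c("informative", "random"),
                                 threshold = 0.001, seed = 1L) {
  mode <- match.arg(mode)
  if (!"block_id" %in% names(study) || anyNA(study$block_id)) {
    stop("'study' has no complete block_id column; supply LD blocks or a precomputed is_training flag",
         call. = FALSE)
  }
  z <- z_matrix(study)
  zmin <- do.call(pmin, as.data.frame(z))
  blocks <- split(seq_len(nrow(study)), study$block_id)
  chosen <- integer(length(blocks))
  with_seed(substream_seed(seed, "snp_select"), {
    for (b in seq_along(blocks)) {
      rows <- blocks[[b]]
      bm <- min(zmin[rows])
      if (mode == "informative" && bm < threshold) {
        chosen[b] <- rows[which.min(zmin[rows])]
      } else {
        chosen[b] <- rows[sample.int(length(rows), 1L)]
      }
    }
  })
  is_training <- logical(nrow(study))
  is_training[chosen] <- TRUE
  structure(list(
    is_training = is_training,
    chosen = data.table::data.table(block_id = as.integer(names(blocks)),
                                    snp = study$snp[chosen]),
    mode = mode),
    class = "training_selection")
}
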