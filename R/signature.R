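#' RPKM expression table averaged per cell type
#'
#' Reads per kilobase per million mapped reads:
#' `RPKM = count * 1e9 / (length_bp * sample_total)`, computed per sample and
#' then averaged (arithmetic mean) over each cell type's replicates.
#'
#' @inheritParams size_factors
#' @param meta Sample metadata with columns `sample` and `celltype`.
#' @param lengths A data frame with columns `gene_id` and `length` (bp), or a
#'   named numeric vector of gene lengths.
#' @param celltype_col Metadata column naming the cell type of each sample.
#' @return A tibble with `gene_id` and one RPKM column per cell type.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10L)
#' meta <- tibble::tibble(sample = "s1", celltype = "EE")
#' rpkm(counts, meta, c(g1 = 1000))  # 10 reads, 1 kb, but s1 total is 10
#' @export
rpkm <- function(counts, meta, lengths, celltype_col = "celltype") {
  m <- as_count_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$gene_id)
  }
  len <- lengths[rownames(m)]
  if (anyNA(len)) {
    abort(sprintf("missing gene lengths for: %s",
                  paste(head(rownames(m)[is.na(len)]), collapse = ", ")))
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  totals <- colSums(m)
  if (any(totals <= 0)) abort("every sample must have a positive total count")
  r <- m * 1e9 / outer(as.numeric(len), totals)
  types <- sample_groups(colnames(m), meta, celltype_col)
  by_type <- vapply(split(seq_along(types), types),
                    function(j) rowMeans(r[, j, drop = FALSE]),
                    numeric(nrow(r)))
  if (nrow(r) == 1) by_type <- matrix(by_type, nrow = 1,
                                      dimnames = list(NULL, names(split(seq_along(types), types))))
  matrix_to_tibble(`rownames<-`(by_type, rownames(m)), id_col = "gene_id")
}

#' Cell-type signature genes from RPKM profiles
#'
#' For each focal cell type, genes below the RPKM floor in that type are
#' removed, the rest are scored by
#' `score = log10(RPKM) / 5 + fold_change` with
#' `fold_change = RPKM_focal / mean(RPKM over all cell types)`, and the
#' top `top_n` by score become that type's signature. The score combines
#' absolute abundance (the log term, `RPKM` being the focal type's value) with
#' comparative enrichment (the fold change over the across-type mean).
#'
#' The floor is applied before the log, so the log10 argument is always at
#' least `min_rpkm`. Ties at the `top_n` boundary are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param rpkm_table Output of [rpkm()]: `gene_id` plus one column per cell
#'   type.
#' @param min_rpkm Focal-type RPKM floor; genes strictly below it are dropped
#'   (default 3.5).
#' @param top_n Signature size per cell type (default 250).
#' @return A tibble with columns `celltype`, `gene_id`, `rpkm`,
#'   `fold_change`, `score`, `rank`, at most `top_n` rows per cell type,
#'   ordered by descending score within type.
#' @examples
#' tab <- tibble::tibble(gene_id = "g1", EE = 100, progenitor = 10, EC = 10)
#' score_signatures(tab)  # fold change 2.5, score log10(100)/5 + 2.5 = 2.9
#' @export
score_signatures <- function(rpkm_table, min_rpkm = 3.5, top_n = 250) {
  types <- setdiff(names(rpkm_table), "gene_id")
  if (length(types) < 2) abort("need at least two cell-type columns")
  long <- tidyr::pivot_longer(rpkm_table, dplyr::all_of(types),
                              names_to = "celltype", values_to = "rpkm")
  type_mean <- rowMeans(as.matrix(rpkm_table[types]))
  long$across_mean <- rep(type_mean, each = length(types))

  scored <- long |>
    dplyr::filter(.data$rpkm >= min_rpkm) |>
    dplyr::mutate(fold_change = .data$rpkm / .data$across_mean,
                  score = log10(.data$rpkm) / 5 + .data$fold_change) |>
    dplyr::arrange(.data$celltype, dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::group_by(.data$celltype) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("celltype", "gene_id", "rpkm", "fold_change", "score", "rank")

  empty <- setdiff(types, unique(scored$celltype))
  if (length(empty) > 0) {
    warn(sprintf("all genes fell below the %.3g RPKM floor for: %s",
                 min_rpkm, paste(empty, collapse = ", ")))
  }
  scored
}

#' Signature tibble to named gene-set list
#'
#' Convenience conversion for [permutation_nes()] and GMT output: one
#' character vector of gene ids per cell type.
#'
#' @param signatures Output of [score_signatures()].
#' @return A named list of character vectors.
#' @export
signature_sets <- function(signatures) {
  split(signatures$gene_id, signatures$celltype)
}
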