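#' Call direct TF targets from binding and expression
#'
#' A gene is a direct-target call when it is bound (assigned to at least one
#' significant DamID peak) and transcriptionally altered upon TF depletion.
#' Direction `"down"` (reduced in the knockdown) marks candidate activated
#' targets, `"up"` candidate repressed ones. The table covers the union of
#' the bound genes and the tested DE genes; the DE universe recorded in
#' [glance()] is the genes with a defined adjusted p.
#'
#' @param damid_genes Character vector of bound gene ids — typically
#'   `attr(annotate_peaks(...), "genes")` — or an annotated peak tibble,
#'   from which the ids are pulled.
#' @param de A `de_result` from [nb_wald_test()] on the depletion experiment.
#' @param padj_max,min_abs_log2fc Thresholds passed to [call_de()].
#' @return A `target_calls` object; [tidy()] gives one row per gene
#'   (`gene_id`, `bound`, `de_direction`, `target`, `log2fc`, `padj`),
#'   [glance()] the summary counts (`n_targets = n_down + n_up`).
#' @export
call_targets <- function(damid_genes, de, padj_max = 0.01,
                         min_abs_log2fc = 0.5) {
  if (is.data.frame(damid_genes)) {
    damid_genes <- attr(damid_genes, "genes") %||%
      sort(unique(unlist(damid_genes$gene_ids)))
  }
  damid_genes <- unique(as.character(damid_genes))
  if (length(damid_genes) == 0) {
    warn("no bound genes supplied; target set is empty")
  }
  tab <- if (inherits(de, "de_result")) de$table else tibble::as_tibble(de)
  calls <- call_de(de, padj_max, min_abs_log2fc)

  universe <- union(damid_genes, tab$feature_id)
  out <- tibble::tibble(gene_id = sort(universe)) |>
    dplyr::left_join(dplyr::select(tab, gene_id = "feature_id",
                                   "log2fc", "padj"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::select(calls, gene_id = "feature_id",
                                   de_direction = "direction"),
                     by = "gene_id") |>
    dplyr::mutate(bound = .data$gene_id %in% damid_genes,
                  de_direction = dplyr::coalesce(.data$de_direction, "none"),
                  target = .data$bound & .data$de_direction != "none") |>
    dplyr::select("gene_id", "bound", "de_direction", "target",
                  "log2fc", "padj")

  structure(list(table = out,
                 n_tested = sum(!is.na(tab$padj)),
                 padj_max = padj_max,
                 min_abs_log2fc = min_abs_log2fc),
            class = "target_calls")
}

#' @export
tidy.target_calls <- function(x, ...) x$table

#' @export
glance.target_calls <- function(x, ...) {
  tgt <- x$table[x$table$target, , drop = FALSE]
  tibble::tibble(n_bound = sum(x$table$bound),
                 n_de_universe = x$n_tested,
                 n_targets = nrow(tgt),
                 n_down = sum(tgt$de_direction == "down"),
                 n_up = sum(tgt$de_direction == "up"))
}

#' @export
print.target_calls <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<target_calls> %d bound genes x %d tested -> %d targets (%d down, %d up)\n",
              g$n_bound, g$n_de_universe, g$n_targets, g$n_down, g$n_up))
  invisible(x)
}

#' Overlap of TF targets with a cell-type signature
#'
#' Reports how many of a cell type's signature genes are direct targets,
#' what fraction of that intersection is down-regulated upon depletion, and
#' (when the intersection is nonempty) a gene-set-permutation GSEA of the
#' intersection against the ranked depletion DE list — the "are the bound
#' identity genes collectively down?" question.
#'
#' @param targets A `target_calls` from [call_targets()].
#' @param signature Character vector of signature gene ids (or a
#'   [score_signatures()] tibble filtered to one cell type).
#' @param ranked Ranked depletion DE list from [rank_genes()].
#' @param n_perm,seed Passed to [gsea_preranked()].
#' @return A list: `overlap` (count), `overlap_genes`, `down_fraction`
#'   (share of the intersection called down), and `gsea` (a `gsea_result`,
#'   or `NULL` with a notice when the intersection is empty).
#' @export
signature_overlap <- function(targets, signature, ranked,
                              n_perm = 1000, seed = NULL) {
  if (is.data.frame(signature)) signature <- signature$gene_id
  if (length(signature) == 0) abort("empty signature")
  tab <- tidy(targets)
  target_genes <- tab$gene_id[tab$target]
  inter <- intersect(target_genes, signature)
  if (length(inter) == 0) {
    inform("no overlap between targets and signature; GSEA skipped")
    return(list(overlap = 0L, overlap_genes = character(0),
                down_fraction = NA_real_, gsea = NULL))
  }
  down <- tab$gene_id[tab$target & tab$de_direction == "down"]
  res <- gsea_preranked(ranked, list(target_signature = inter),
                        n_perm = n_perm, seed = seed)
  list(overlap = length(inter),
       overlap_genes = sort(inter),
       down_fraction = length(intersect(inter, down)) / length(inter),
       gsea = res)
}
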