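# ggplot2 views of the result objects.

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param padj_max,min_abs_log2fc Thresholds used to colour the calls.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, padj_max = 0.01,
                               min_abs_log2fc = 0.5, ...) {
  tab <- tidy(object) |>
    dplyr::filter(!is.na(.data$padj)) |>
    dplyr::mutate(call = dplyr::case_when(
      .data$padj < padj_max & .data$log2fc > min_abs_log2fc ~ "up",
      .data$padj < padj_max & .data$log2fc < -min_abs_log2fc ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc,
                                    -log10(pmax(.data$pvalue, 1e-300)),
                                    colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2e6da4",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change",
                  y = "-log10 p",
                  colour = NULL,
                  title = sprintf("%s vs %s", object$treatment,
                                  object$control)) +
    ggplot2::theme_minimal()
}

#' Running-sum plot of a GSEA result
#'
#' @param object A `gsea_result`.
#' @param set Which set to draw (default: the first).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gsea_result <- function(object, set = NULL, ...) {
  set <- set %||% object$results$set[1]
  run <- object$running[[set]]
  if (is.null(run)) abort(sprintf("no running sum stored for set '%s'", set))
  row <- object$results[object$results$set == set, ]
  ggplot2::ggplot(run, ggplot2::aes(.data$position, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#2e6da4") +
    ggplot2::geom_rug(data = run[run$hit, ], sides = "b",
                      alpha = 0.4, length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in ordered list", y = "running enrichment score",
                  title = sprintf("%s: ES %.3f, NES %.3f, p %.3g",
                                  set, row$es, row$nes, row$pvalue)) +
    ggplot2::theme_minimal()
}

#' Replicate-correlation heatmap
#'
#' @param corr A correlation matrix from [replicate_correlation()].
#' @return A ggplot.
#' @export
plot_replicate_correlation <- function(corr) {
  long <- matrix_to_tibble(corr, id_col = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Signature score distribution per cell type
#'
#' @param signatures Output of [score_signatures()].
#' @return A ggplot.
#' @export
plot_signature_scores <- function(signatures) {
  ggplot2::ggplot(signatures, ggplot2::aes(.data$rank, .data$score,
                                           colour = .data$celltype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank within cell type", y = "signature score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
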