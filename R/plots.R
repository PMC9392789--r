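# ggplot2 visualisations for the main result types.

#' Quadrant scatterplot of tissue cell-cycle activity
#'
#' Normal-tissue median score (x) against tumour median score (y), both
#' min-max scaled across tissues, with the quadrant threshold drawn as
#' dashed lines and tissues labelled.
#'
#' @param object A `bccs_quadrants` tibble from [classify_quadrants()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bccs_quadrants <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.5
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$median_normal_scaled,
                               y = .data$median_tumor_scaled,
                               colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$tissue),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(xlim = c(-0.05, 1.05), ylim = c(-0.05, 1.1)) +
    ggplot2::labs(x = "Median normal score (scaled)",
                  y = "Median tumour score (scaled)", colour = "Quadrant") +
    ggplot2::theme_minimal()
}

#' Volcano plot of moderated DE results
#'
#' @param object A `bccs_de` fit.
#' @param ... Ignored.
#' @return A ggplot object with the fold-change and FDR cuts drawn and
#'   significant genes highlighted.
#' @export
autoplot.bccs_de <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$log2_fc, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-object$lfc, object$lfc),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (Group 2 vs Group 1)",
                  y = "-log10 p", colour = "Significant") +
    ggplot2::theme_minimal()
}

#' Embedding scatterplot
#'
#' @param object A `bccs_embedding` from [run_pca()] or [run_umap()].
#' @param labels Optional named character vector (sample id -> label) used
#'   to colour points, e.g. study or tissue.
#' @param ... Ignored.
#' @return A ggplot object of the first two dimensions.
#' @export
autoplot.bccs_embedding <- function(object, labels = NULL, ...) {
  tab <- as_tibble(object)
  tab$label <- if (is.null(labels)) "sample" else unname(labels[tab$sample_id])
  ev <- attr(object, "explained_variance")
  axis_lab <- function(i) {
    if (!is.null(ev)) sprintf("%s %d (%.1f%%)", attr(object, "method"), i, 100 * ev[i])
    else sprintf("%s %d", attr(object, "method"), i)
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = axis_lab(1), y = axis_lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Barplot of gene correlations to the corrected score
#'
#' @param correlations Output of [correlate_genes_to_bccs()].
#' @param n_top Number of genes shown from each end (default 10).
#' @param rho_ref Reference line (default 0.3).
#' @return A ggplot object.
#' @export
plot_bccs_correlations <- function(correlations, n_top = 10, rho_ref = 0.3) {
  tab <- correlations |>
    filter(!is.na(.data$rho)) |>
    arrange(desc(.data$rho))
  tab <- bind_rows(head(tab, n_top), utils::tail(tab, n_top)) |>
    distinct() |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rho, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(-rho_ref, rho_ref),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Spearman rho to corrected score", y = NULL) +
    ggplot2::theme_minimal()
}
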