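#' Volcano plot of a differential-expression fit
#'
#' @param object An `nb_de` object.
#' @param fc_threshold,fdr_threshold Thresholds drawn and used to colour
#'   DEGs (defaults 2 and 0.01, as in [apply_deg_thresholds()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_de
#' @export
autoplot.nb_de <- function(object, fc_threshold = 2, fdr_threshold = 0.01, ...) {
  df <- apply_deg_thresholds(object, fc_threshold, fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 name = "DEG") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' Bar plot of genomic-context classes
#'
#' @param calls The context-call tibble from [classify_context()], or the
#'   list returned by [classify_all()].
#' @return A ggplot object.
#' @export
plot_context_classes <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- calls$calls
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$class, fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "genomic context", y = "candidate lncRNAs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Histogram of gene projection identities
#'
#' @param projection The `genes` tibble from [project_genes()] (or the
#'   list itself).
#' @param identity_threshold Threshold line to draw (default 0.60).
#' @return A ggplot object.
#' @export
plot_projection_identity <- function(projection, identity_threshold = 0.60) {
  if (is.list(projection) && !is.data.frame(projection)) {
    projection <- projection$genes
  }
  df <- dplyr::filter(projection, !is.na(.data$gene_identity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_identity,
                                   fill = .data$ortholog_call)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = identity_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "gene alignment identity", y = "genes",
                  fill = "ortholog call") +
    ggplot2::theme_minimal()
}
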