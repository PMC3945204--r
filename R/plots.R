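#' Plot methods for diagnostics and results
#'
#' `autoplot()` methods: a PC1/PC2 scatter coloured by batch for `kd_pca`, a
#' volcano plot for `kd_de`, and a boxplot of the per-bin co-occupancy
#' enrichments for `kd_cooccupancy`. `plot_rle()` draws relative
#' log-expression boxes per array.
#'
#' @param object,x Result object.
#' @param fdr FDR threshold highlighted in the volcano plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name kdbind-plots
NULL

#' @rdname kdbind-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.kd_pca <- function(object, ...) {
  df <- object$scores
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$var_frac[i])
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$batch)),
                        size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = "batch") +
    ggplot2::theme_minimal()
}

#' @rdname kdbind-plots
#' @export
autoplot.kd_de <- function(object, fdr = 0.05, ...) {
  df <- as_tibble(object)
  df$de <- df$q <= fdr
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$de), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "goldenrod")) +
    ggplot2::labs(title = attr(object, "experiment"),
                  x = "log2 fold-change", y = "-log10 p",
                  colour = sprintf("DE (FDR %g%%)", 100 * fdr)) +
    ggplot2::theme_minimal()
}

#' @rdname kdbind-plots
#' @export
autoplot.kd_cooccupancy <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(factor(.data$bin), .data$enrichment)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = "shared DE-factor fraction (quintile)",
                  y = "co-occupancy enrichment") +
    ggplot2::theme_minimal()
}

#' @rdname kdbind-plots
#' @param mat A matrix or [kd_expression()] for `plot_rle()`.
#' @export
plot_rle <- function(mat) {
  v <- if (inherits(mat, "kd_expression")) mat$values else as.matrix(mat)
  dev <- v - apply(v, 1, median)
  df <- tidyr::pivot_longer(as_tibble(dev), dplyr::everything(),
                            names_to = "array_id", values_to = "rle")
  ggplot2::ggplot(df, ggplot2::aes(.data$array_id, .data$rle)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "relative log expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
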