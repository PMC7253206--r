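#' Scatter of parental vs hybrid allelic fold change by category
#'
#' The classic cis/trans dissection plot: each gene's parental log2 fold
#' change (W/C in F0) against its hybrid allelic log2 fold change
#' (W-allele/C-allele in F1), colored by regulatory category. Pure cis
#' genes fall on the diagonal, pure trans genes on the horizontal axis,
#' compensatory genes on the vertical axis.
#'
#' @param object A `regulatory_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regulatory_calls
#' @export
autoplot.regulatory_calls <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$hybrid_log2fc, y = .data$parental_log2fc, color = .data$category)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_hline(yintercept = 0, color = "grey80") +
    ggplot2::geom_vline(xintercept = 0, color = "grey80") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = "Hybrid allelic log2FC (W allele / C allele, F1)",
      y = "Parental log2FC (W / C, F0)",
      color = "Category"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of the degree of dominance
#'
#' Distribution of k for genes (or traits) with defined k, with the
#' additivity interval (-0.25, 0.25) shaded and the transgression bounds at
#' |k| = 1.25 marked.
#'
#' @param x A `dominance_records` tibble.
#' @param limit Plot range on |k| (default 2, the usual display window).
#' @param binwidth Histogram bin width (default 0.1).
#' @return A ggplot.
#' @export
plot_k_distribution <- function(x, limit = 2, binwidth = 0.1) {
  df <- x %>% filter(!is.na(.data$k), abs(.data$k) <= limit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::annotate("rect",
      xmin = -0.25, xmax = 0.25, ymin = -Inf, ymax = Inf,
      fill = "purple", alpha = 0.15
    ) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::geom_vline(xintercept = c(-1.25, 1.25), linetype = "dotted") +
    ggplot2::labs(
      x = "Degree of dominance k (positive: cultivated pattern recessive)",
      y = "Genes"
    ) +
    ggplot2::theme_minimal()
}

#' Mean cis percentage per effect-size bin
#'
#' @param bins Output of [cis_percentage_bins()].
#' @return A ggplot.
#' @export
plot_cis_percentage <- function(bins) {
  df <- bins %>% filter(!is.na(.data$mean_cis_percentage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_cis_percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "|parental log2FC| bin",
      y = "Mean cis percentage (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Scores plot for a trait PCA
#'
#' @param object A `trait_pca` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 (points colored by genotype when a
#'   `genotype` column is present in the scores).
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, ...) {
  sc <- object$scores
  ve <- object$variance_explained
  aes <- if ("genotype" %in% names(sc)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data$genotype)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}
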