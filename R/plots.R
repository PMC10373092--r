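#' Plot the global specificity landscape
#'
#' Density of per-gene phi for each threshold column of a specificity
#' table; a bimodal curve (modes near 0 and 1) is the expected signature
#' of a compendium dominated by ubiquitous plus restricted genes.
#'
#' @param spec A specificity table from [specificity_table()].
#' @return A ggplot object.
#' @export
plot_phi_density <- function(spec) {
  phi_cols <- grep("^phi_", names(spec), value = TRUE)
  if (!length(phi_cols)) abort("no phi_* columns to plot")
  long <- tidyr::pivot_longer(spec[c("gene_id", phi_cols)],
                              dplyr::all_of(phi_cols),
                              names_to = "threshold", values_to = "phi")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phi,
                                     colour = .data$threshold)) +
    ggplot2::geom_density(adjust = 0.5) +
    ggplot2::labs(x = expression(phi ~ "(global expression specificity)"),
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Plot per-gene dynamic ranges
#'
#' Draws each selected gene's percentile vector (Q5..Q95 of its quantile
#' ranks) as a line: flat-high lines are stable ubiquitous genes, lines
#' hugging zero with a late rise are restricted genes.
#'
#' @param drm A `ueg_dynrange` table.
#' @param genes Optional gene ids to show (default: first 20).
#' @return A ggplot object.
#' @export
plot_dynamic_range <- function(drm, genes = NULL) {
  grid <- attr(drm, "grid", exact = TRUE)
  genes <- genes %||% head(drm$gene_id, 20)
  sub <- filter(drm, .data$gene_id %in% genes)
  long <- tidyr::pivot_longer(sub[c("gene_id", sprintf("q%02d", grid))],
                              -"gene_id", names_to = "percentile",
                              values_to = "rank")
  long$percentile <- as.integer(sub("^q", "", long$percentile))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percentile, y = .data$rank,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "percentile of samples", y = "quantile rank") +
    ggplot2::theme_minimal()
}

#' Plot transcriptome sizes
#'
#' @param sizes Output of [transcriptome_sizes()].
#' @return A ggplot object.
#' @export
plot_transcriptome_sizes <- function(sizes) {
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$n_expressed)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "expressed genes per sample", y = "density") +
    ggplot2::theme_minimal()
}

#' PCA view of a percentile clustering
#'
#' Projects the dynamic-range feature matrix on its first two principal
#' components and colours genes by cluster.
#'
#' @param object A `ueg_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ueg_clusters <- function(object, ...) {
  pc <- prcomp(object$features, scale. = FALSE)
  df <- tibble(
    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
    cluster = factor(object$assignments$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot a candidate evaluation report
#'
#' Specificity versus variability for each candidate, coloured by verdict
#' (the plane in which constitutive, variable-ubiquitous and restricted
#' candidates separate).
#'
#' @param report A `candidate_report` from [evaluate_candidates()].
#' @return A ggplot object.
#' @export
plot_candidates <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$phi, y = .data$iqr,
                                       colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(phi), y = "IQR (variability)") +
    ggplot2::theme_minimal()
}
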