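# ggplot2 views of the result objects. Each plot_* has an autoplot()
# counterpart on the corresponding class.

#' Plot the clustering QC embedding
#'
#' Samples in the first two principal components, coloured by cell type and
#' shaped by lineage.
#'
#' @param qc An `embedding_qc` (or its `embedding` tibble).
#' @return A ggplot.
#' @export
plot_embedding <- function(qc) {
  emb <- if (inherits(qc, "embedding_qc")) qc$embedding else as_tibble(qc)
  ggplot(emb, aes(x = .data$dim1, y = .data$dim2,
                  colour = .data$cell_type, shape = .data$lineage)) +
    geom_point(alpha = 0.8, size = 2) +
    labs(x = "PC1", y = "PC2", colour = "cell type", shape = "lineage",
         title = if (inherits(qc, "embedding_qc")) {
           sprintf("Clustering QC (ARI = %.2f)", qc$ari)
         } else NULL) +
    theme_minimal()
}

#' @export
autoplot.embedding_qc <- function(object, ...) plot_embedding(object)

#' Plot peak-geometry distributions by class
#'
#' Boxplots of peak width and minimum TSS distance per OCR class, annotated
#' with the Mann-Whitney p-values.
#'
#' @param report A `geometry_report`.
#' @return A ggplot (facetted width / distance).
#' @export
plot_peak_geometry <- function(report) {
  stopifnot(inherits(report, "geometry_report"))
  long <- report$data |>
    pivot_longer(c("width", "min_abs_distance"),
                 names_to = "metric", values_to = "value") |>
    filter(!is.na(.data$value)) |>
    mutate(metric = recode(.data$metric, width = "peak width (bp)",
                           min_abs_distance = "distance to TSS (bp)"))
  p_lab <- paste(sprintf("%s p = %.2g", report$tests$metric,
                         report$tests$p_value), collapse = "; ")
  ggplot(long, aes(x = .data$class, y = .data$value, fill = .data$class)) +
    geom_boxplot(outlier.alpha = 0.3) +
    facet_wrap(~metric, scales = "free_y") +
    scale_y_log10() +
    labs(x = NULL, y = NULL, subtitle = p_lab) +
    guides(fill = "none") +
    theme_minimal()
}

#' @export
autoplot.geometry_report <- function(object, ...) plot_peak_geometry(object)

#' Scatter plot of potential TFs: expression vs enrichment
#'
#' @param records A [potential_tfs()] (or [motif_enrichment()] with
#'   `mean_tpm` attached) table.
#' @return A ggplot of mean TPM against the enrichment score with TF labels.
#' @export
plot_tf_scatter <- function(records) {
  ggplot(records, aes(x = .data$mean_tpm, y = .data$enrichment_score)) +
    geom_point(colour = "steelblue", size = 2) +
    geom_text(aes(label = .data$tf_gene), vjust = -0.6, size = 3) +
    scale_x_log10() +
    labs(x = "mean TPM", y = "enrichment score (-log10 p)") +
    theme_minimal()
}

#' Plot occupancy fractions per motif in two peak sets
#'
#' @param comparison An `occupancy_comparison`.
#' @param labels Names for the two sets.
#' @return A grouped bar chart with the test p-value in the subtitle.
#' @export
plot_occupancy_fractions <- function(comparison, labels = c("set A", "set B")) {
  stopifnot(inherits(comparison, "occupancy_comparison"))
  long <- comparison$fractions |>
    pivot_longer(c("frac_a", "frac_b"), names_to = "set",
                 values_to = "fraction") |>
    mutate(set = recode(.data$set, frac_a = labels[1], frac_b = labels[2]))
  ggplot(long, aes(x = .data$motif_id, y = .data$fraction, fill = .data$set)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "fraction of OCRs with a hit", fill = NULL,
         subtitle = sprintf("%s p = %.3g", comparison$test$method,
                            comparison$test$p_value)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.occupancy_comparison <- function(object, ...) {
  plot_occupancy_fractions(object)
}

#' @rdname tidy.scan_calibration
#' @export
tidy.scan_calibration <- function(x, ...) {
  tibble(motif_id = x$motif_id, tf_name = x$tf_name,
         threshold_score = x$threshold_score,
         attained_pvalue = x$attained_pvalue, p_target = x$p_target,
         precision = x$precision)
}

#' Tidy a geometry report
#'
#' @param x A `geometry_report` (or `scan_calibration`).
#' @param ... Unused.
#' @return Tibble of the class-comparison tests joined with the summaries.
#' @rdname tidy.scan_calibration
#' @export
tidy.geometry_report <- function(x, ...) {
  x$tests |> select("metric", "statistic", "p_value", "n1", "n2")
}
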