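#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Boxplot of per-sample window methylation
#'
#' The boxplot-of-window-means display used to compare global methylation
#' between groups (e.g. young vs old, WT vs Tg).
#'
#' @param matrix Wide methylation matrix from [aggregate_regions()].
#' @param groups Optional named vector mapping sample ids to group labels.
#' @return A ggplot object.
#' @export
plot_global_methylation <- function(matrix, groups = NULL) {
  long <- tidyr::pivot_longer(matrix, cols = all_of(matrix_sample_cols(matrix)),
                              names_to = "sample_id", values_to = "level") |>
    filter(!is.na(.data$level))
  if (!is.null(groups)) long$group <- groups[long$sample_id]
  p <- ggplot(long, aes(x = .data$sample_id, y = .data$level)) +
    geom_boxplot(if (!is.null(groups)) aes(fill = .data$group)) +
    labs(x = NULL, y = "mean CpG methylation per window") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  p
}

#' @rdname pca_samples
#' @param object A `methyl_pca` object.
#' @param groups Optional named vector mapping sample ids to group labels.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.methyl_pca <- function(object, groups = NULL, ...) {
  sc <- object$scores
  if (!is.null(groups)) sc$group <- groups[sc$sample_id]
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(if (!is.null(groups)) aes(color = .data$group), size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)",
                     100 * (object$var_explained[2] %||% 0))) +
    theme_minimal()
}

#' Heatmap of a (z-scored) methylation matrix
#'
#' Tile heatmap of regions by samples, the display used for DMR z-score
#' panels. Rows are ordered by correlation-distance complete-linkage
#' clustering when possible.
#'
#' @param matrix Wide methylation matrix (typically from [zscore_rows()]).
#' @param cluster_rows Reorder rows by hierarchical clustering.
#' @return A ggplot object.
#' @export
plot_dmr_heatmap <- function(matrix, cluster_rows = TRUE) {
  if (cluster_rows && nrow(matrix) > 2) {
    ord <- tryCatch(hcluster(matrix, "correlation", on = "regions")$leaf_order,
                    error = function(e) matrix$region_id)
    matrix <- matrix[match(ord, matrix$region_id), , drop = FALSE]
  }
  long <- tidyr::pivot_longer(matrix, cols = all_of(matrix_sample_cols(matrix)),
                              names_to = "sample_id", values_to = "z")
  long$region_id <- factor(long$region_id, levels = rev(unique(matrix$region_id)))
  ggplot(long, aes(x = .data$sample_id, y = .data$region_id,
                   fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    theme(axis.text.y = element_blank(),
          axis.text.x = element_text(angle = 45, hjust = 1))
}

#' MIAMI scatter of HpaII vs MspI log-ratios
#'
#' The two-enzyme scatter: methylation-insensitive MspI log-ratios on the
#' vertical axis against methylation-sensitive HpaII log-ratios on the
#' horizontal axis, colored by methylation class; dashed lines mark the
#' classification thresholds.
#'
#' @param table Classified MIAMI probe tibble.
#' @param thr Thresholds used (drawn as vertical dashed lines).
#' @return A ggplot object.
#' @export
plot_miami <- function(table, thr = miami_thresholds()) {
  ggplot(table, aes(x = .data$log_hpaii, y = .data$log_mspi,
                    color = .data$meth_class)) +
    geom_point(alpha = 0.4, size = 0.6) +
    geom_vline(xintercept = log(c(thr$low, thr$high)), linetype = "dashed") +
    scale_color_manual(values = c(hypermethylated = "#b2182b",
                                  hypomethylated = "#2166ac",
                                  unchanged = "grey60")) +
    labs(x = "HpaII log-ratio", y = "MspI log-ratio", color = NULL) +
    theme_minimal()
}

#' @rdname elas_table
#' @param object An `elas_result` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.elas_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$tissue, y = .data$mean_elas, fill = .data$genotype)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean_elas - .data$se_elas,
                      ymax = .data$mean_elas + .data$se_elas),
                  position = position_dodge(width = 0.8), width = 0.2) +
    labs(x = NULL, y = "ElaS (mean ± SE)", fill = NULL) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
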