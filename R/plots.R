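## ggplot2 views of the report tables.  Thin layers over the tibbles; all
## numbers come from the reporting functions themselves.

#' Bar plot of ROI-level encoding performance
#'
#' Mirrors the classic ROI summary figure: one bar per model per ROI
#' showing the mean accuracy of the pooled top voxels, with the median
#' noise ceiling as a horizontal reference when available.
#'
#' @param tbl The `roi_summary` table of an [run_pipeline()] report (or
#'   [roi_summary()] output with a `model` column).
#' @return A ggplot.
#' @export
plot_roi_summary <- function(tbl) {
  roi_order <- c("V1", "V2", "V3", "V4", "LOC", "PPA", "FFA")
  tbl <- mutate(tbl, roi = factor(.data$roi, levels = intersect(roi_order, unique(.data$roi))))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$roi, y = .data$mean_accuracy,
                                         fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy - sqrt(.data$var_accuracy),
                                        ymax = .data$mean_accuracy + sqrt(.data$var_accuracy)),
                           position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Prediction accuracy (Pearson r)",
                  fill = "Model") +
    ggplot2::theme_minimal()
  if ("median_ceiling" %in% names(tbl)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median_ceiling, ymax = .data$median_ceiling),
      linetype = 1, linewidth = 0.8, width = 0.9, colour = "black")
  }
  p
}

#' Stacked bars of optimal-layer distributions per ROI
#'
#' @param tbl The `layer_distribution` table of a report.
#' @return A ggplot.
#' @export
plot_layer_distribution <- function(tbl) {
  roi_order <- c("V1", "V2", "V3", "V4", "LOC", "PPA", "FFA")
  tbl <- tbl |>
    filter(!.data$empty) |>
    mutate(roi = factor(.data$roi, levels = intersect(roi_order, unique(.data$roi))),
           layer = factor(.data$layer))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$roi, y = .data$fraction,
                                         fill = .data$layer)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(direction = -1) +
    ggplot2::labs(x = NULL, y = "Fraction of accurately predicted voxels",
                  fill = "Optimal layer") +
    ggplot2::theme_minimal()
  if ("model" %in% names(tbl)) p <- p + ggplot2::facet_wrap(~model)
  p
}

#' Layer-by-layer accuracy curves per ROI
#'
#' @param tbl The `layer_accuracy` table of a report.
#' @return A ggplot.
#' @export
plot_layer_accuracy <- function(tbl) {
  roi_order <- c("V1", "V2", "V3", "V4", "LOC", "PPA", "FFA")
  tbl <- mutate(tbl, roi = factor(.data$roi, levels = intersect(roi_order, unique(.data$roi))))
  aes_base <- if ("model" %in% names(tbl)) {
    ggplot2::aes(x = .data$layer, y = .data$mean_accuracy, colour = .data$model)
  } else {
    ggplot2::aes(x = .data$layer, y = .data$mean_accuracy)
  }
  ggplot2::ggplot(tbl, aes_base) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "Feature layer", y = "Mean accuracy of top voxels",
                  colour = "Model") +
    ggplot2::theme_minimal()
}

#' Heatmap of a representational dissimilarity matrix
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$matrix, responseName = "dissimilarity"))
  names(df)[1:2] <- c("stim_i", "stim_j")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stim_i, y = .data$stim_j,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r",
                  title = object$label) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
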