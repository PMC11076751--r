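# ggplot2 visualizations for annotations and comparisons.

region_df <- function(region, what) {
  purrr::imap_dfr(region$rings, function(r, i) {
    tibble(x = c(r[, 1], r[1, 1]), y = c(r[, 2], r[1, 2]),
           ring = paste0(what, "_", i), element = what)
  })
}

#' Plot an annotation set over the tumor silhouette
#'
#' Draws the painted region, incisions, burr holes and craniotomy in the
#' assessment plane, with the tumor silhouette underneath for reference.
#'
#' @param object An `annotation_set`.
#' @param silhouette Optional tumor silhouette ([region2d()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot annotation_set
#' @export
autoplot.annotation_set <- function(object, silhouette = NULL, ...) {
  layers <- list()
  df_sil <- if (!is.null(silhouette)) region_df(silhouette, "tumor silhouette")
  df_p <- region_df(object$painted, "painted")
  quad_df <- tibble(x = c(object$craniotomy$coords[, 1], object$craniotomy$coords[1, 1]),
                    y = c(object$craniotomy$coords[, 2], object$craniotomy$coords[1, 2]))
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(silhouette)) {
    p <- p + ggplot2::geom_polygon(data = df_sil, ggplot2::aes(group = .data$ring),
                                   fill = "grey70", alpha = 0.6)
  }
  p +
    ggplot2::geom_polygon(data = df_p, ggplot2::aes(group = .data$ring),
                          fill = "firebrick", alpha = 0.3, colour = "firebrick") +
    ggplot2::geom_path(data = quad_df, colour = "navy", linewidth = 0.8) +
    ggplot2::geom_path(data = tibble(x = object$linear_incision$coords[, 1],
                                     y = object$linear_incision$coords[, 2]),
                       colour = "darkgreen", linewidth = 0.8) +
    ggplot2::geom_path(data = tibble(x = object$u_incision$coords[, 1],
                                     y = object$u_incision$coords[, 2]),
                       colour = "orange3", linewidth = 0.8) +
    ggplot2::geom_point(data = tibble(x = object$burr_holes[, 1],
                                      y = object$burr_holes[, 2]),
                        shape = 21, fill = "white", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = sprintf("Annotation set (%s)", object$assessment)) +
    ggplot2::theme_minimal()
}

#' Paired metric change between assessments
#'
#' Spaghetti + box plot of one metric at AA1 and AA2, lines joining each
#' participant's pair.
#'
#' @param metrics Metrics tibble from [assess_cohort()].
#' @param metric Metric column name.
#' @return A ggplot.
#' @export
plot_metric_change <- function(metrics, metric) {
  stopifnot(metric %in% names(metrics))
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$assessment,
                                        y = .data[[metric]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.3, colour = "grey40") +
    ggplot2::geom_boxplot(width = 0.25, outlier.shape = NA, fill = "steelblue",
                          alpha = 0.4) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Overview plot of a comparison table
#'
#' One panel per metric showing the p-value of the paired AA1 vs AA2 test;
#' the dashed line marks the significance level.
#'
#' @param object A `planning_comparison` tibble.
#' @param alpha Significance level to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot planning_comparison
#' @export
autoplot.planning_comparison <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_value,
                                       y = stats::reorder(.data$metric, .data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 3) +
    ggplot2::geom_vline(xintercept = alpha, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40")) +
    ggplot2::labs(x = "paired test p-value (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
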