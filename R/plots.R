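# ggplot2 displays for PLV networks and metric tables.

#' Heatmap of a PLV matrix
#'
#' @param object A [plv_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plv_matrix
#' @export
autoplot.plv_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ch1, y = .data$ch2,
                                   fill = .data$plv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLV") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s | %s | %s band", object$subject_id, object$state,
                      object$band),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Network metrics by seizure state
#'
#' Boxplots of one graph metric across states, faceted by band -- the
#' standard display for state comparisons of network properties.
#'
#' @param metrics Metrics tibble from [run_pipeline()] or
#'   [metrics_bundle()] rows.
#' @param metric Which metric column to plot.
#' @return A ggplot object.
#' @export
plot_metrics_by_state <- function(metrics, metric = "global_efficiency") {
  if (!metric %in% names(metrics)) {
    abort_value(paste0("no such metric column: ", metric))
  }
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$state, y = .data[[metric]],
                               fill = .data$state)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Significant edges on the scalp layout
#'
#' Draws the 10-20 electrode positions and the edges flagged significant
#' by an edgewise comparison, coloured by direction of change.
#'
#' @param edge_result Edgewise result tibble (from
#'   [edgewise_two_sample_t()] or [edgewise_state_anova()]).
#' @return A ggplot object.
#' @export
plot_significant_edges <- function(edge_result) {
  xy <- montage_coordinates()
  sig <- edge_result[edge_result$significant %in% TRUE, , drop = FALSE]
  sig <- dplyr::left_join(sig, xy, by = c(ch1 = "channel")) |>
    dplyr::rename(x1 = "x", y1 = "y") |>
    dplyr::left_join(xy, by = c(ch2 = "channel")) |>
    dplyr::rename(x2 = "x", y2 = "y")
  p <- ggplot2::ggplot(xy, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 3, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), vjust = -1,
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(sig) > 0) {
    dir_col <- if ("direction" %in% names(sig)) factor(sig$direction) else "1"
    p <- p + ggplot2::geom_segment(
      data = sig,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, colour = dir_col),
      linewidth = 0.6) +
      ggplot2::scale_colour_manual(
        values = c("-1" = "steelblue", "1" = "firebrick"),
        name = "direction", drop = FALSE)
  }
  p
}
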