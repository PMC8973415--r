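#' Plot graph metrics across proportional thresholds
#'
#' Group-mean metric curves against K, one panel per metric — the standard
#' way to eyeball small-world and efficiency profiles of two cohorts.
#'
#' @param object A metrics tibble with `group`, `k` and metric columns
#'   (e.g. `run_network_arm(...)$metrics`), or a `dbca_metrics` tibble for
#'   a single subject.
#' @param metric_cols Metric columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dbca_metrics <- function(object,
                                  metric_cols = c("cp", "lp", "gamma",
                                                  "lambda", "s",
                                                  "e_glob", "e_loc"),
                                  ...) {
  metric_cols <- intersect(metric_cols, names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  has_group <- "group" %in% names(long)
  if (has_group) {
    long <- long |>
      dplyr::group_by(.data$group, .data$k, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value))
  p <- if (has_group) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$group)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "proportional threshold K", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a 3D map
#'
#' @param map 3D numeric array (e.g. Mean-BEN or a t-map).
#' @param slice Slice index along z (default: middle).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = NULL, title = NULL) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  if (is.null(slice)) slice <- ceiling(dim(map)[3] / 2)
  sl <- map[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
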