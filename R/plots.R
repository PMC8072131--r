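#' Diameter-distribution histogram
#'
#' Histogram of branch diameters, optionally faceted by a grouping column
#' (e.g. age or sex), mirroring the usual presentation of capillary-size
#' distributions.
#'
#' @param branches tibble from [vessel_branches()] (or the pipeline's
#'   branch table).
#' @param by optional name of a grouping column to facet by.
#' @param binwidth_um histogram bin width in um.
#' @return a ggplot object.
#' @export
plot_diameter_distribution <- function(branches, by = NULL,
                                       binwidth_um = 0.5) {
  p <- ggplot2::ggplot(branches,
                       ggplot2::aes(x = .data$mean_diameter_um)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 10, linetype = 2, colour = "red") +
    ggplot2::labs(x = "branch diameter (um)", y = "branches",
                  caption = "dashed line: capillary cutoff (10 um)")
  if (!is.null(by)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", by)))
  }
  p
}

#' Distance-map slice preview
#'
#' Renders one z slice of a vessel distance map with a 0-20 um colour ramp
#' (distances beyond the ramp are clipped), the standard way cell-to-vessel
#' proximity is displayed.
#'
#' @param map a `distance_map` from [vessel_distance_map()].
#' @param z slice index (default: middle slice).
#' @param max_um top of the colour ramp.
#' @return a ggplot object.
#' @export
plot_distance_map <- function(map, z = NULL, max_um = 20) {
  stopifnot(inherits(map, "distance_map"))
  d <- dim(map$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- map$data[, , z]
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x_um <- (df$i - 1) * map$spacing[1]
  df$y_um <- (df$j - 1) * map$spacing[2]
  df$distance_um <- pmin(sl[cbind(df$i, df$j)], max_um)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$distance_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max_um)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "distance (um)",
                  title = sprintf("distance to vessel surface, z slice %d", z))
}

#' Tortuosity summary plot
#'
#' Median branch tortuosity per sample, split by age and sex.
#'
#' @param summary the pipeline's per-sample summary table (needs `age`,
#'   `sex`, `median_tortuosity`).
#' @return a ggplot object.
#' @export
plot_tortuosity_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$age),
                               y = .data$median_tortuosity,
                               colour = .data$sex)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "age group", y = "median branch tortuosity")
}
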