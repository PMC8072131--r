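#' Count cells in every frame of a time-lapse movie
#'
#' Per-frame 2D segmentation: fixed or Otsu thresholding followed by
#' connected-component counting with a minimum area. Frames whose intensity
#' histogram is degenerate (constant frames, e.g. empty fields) are counted
#' as 0 and flagged.
#'
#' @param movie a `timelapse_movie` (see [simulate_timelapse()],
#'   [read_movie()]).
#' @param method `"otsu"` or `"fixed"`; `threshold` required for fixed.
#' @param min_area_px minimum object area in pixels.
#' @return tibble: `frame`, `time_min`, `count`, `flagged`.
#' @export
count_cells_per_frame <- function(movie, method = c("otsu", "fixed"),
                                  threshold = NULL, min_area_px = 9) {
  stopifnot(inherits(movie, "timelapse_movie"))
  method <- match.arg(method)
  if (movie$n_frames < 2) stop("a movie needs at least 2 frames", call. = FALSE)
  rows <- purrr::map(seq_along(movie$frames), function(t) {
    fr <- movie$frames[[t]]
    flagged <- FALSE
    if (method == "fixed") {
      thr <- threshold
      if (is.null(thr)) stop("fixed method requires `threshold`", call. = FALSE)
    } else {
      if (diff(range(fr)) == 0) {
        return(tibble::tibble(frame = t,
                              time_min = (t - 1) * movie$interval_min,
                              count = 0L, flagged = TRUE))
      }
      thr <- otsu_threshold(fr)
    }
    bin <- fr > thr
    lab <- label3d_cpp(as.logical(bin), c(dim(fr), 1L), 26L)
    counts <- tabulate(lab[lab > 0])
    tibble::tibble(frame = t, time_min = (t - 1) * movie$interval_min,
                   count = sum(counts >= min_area_px), flagged = flagged)
  })
  dplyr::bind_rows(rows)
}

#' Population slope of a cell-count series
#'
#' Ordinary least-squares line fit of cell count versus frame index: the
#' slope summarizes net population growth (divisions minus deaths) over the
#' recording, in cells per frame, converted to cells per hour via the
#' capture interval. R-squared of a zero-variance (constant) series is 0 by
#' convention.
#'
#' @param counts integer vector of per-frame counts (>= 2 frames), or the
#'   tibble from [count_cells_per_frame()].
#' @param interval_min capture interval in minutes.
#' @return object of class `population_slope` with fields `slope_per_frame`,
#'   `slope_per_hour`, `intercept`, `r_squared`, `n_frames`,
#'   `interval_min`.
#' @examples
#' fit <- population_slope(c(10, 12, 14, 16), interval_min = 5)
#' fit$slope_per_frame # 2 cells/frame
#' fit$slope_per_hour  # 24 cells/hour
#' @export
population_slope <- function(counts, interval_min = 5) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 2) stop("need at least 2 frames to fit a slope", call. = FALSE)
  t <- seq_len(n) - 1
  fit <- lm(counts ~ t)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(slope_per_frame = slope,
         slope_per_hour = slope * 60 / interval_min,
         intercept = unname(coef(fit)[1]),
         r_squared = r2, n_frames = n, interval_min = interval_min,
         counts = counts),
    class = "population_slope"
  )
}

#' @export
print.population_slope <- function(x, ...) {
  cat(sprintf(
    "<population_slope> %.4g cells/frame (%.4g cells/hour), R^2 = %.3f, %d frames\n",
    x$slope_per_frame, x$slope_per_hour, x$r_squared, x$n_frames))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a population-slope fit
#'
#' @param x a `population_slope`.
#' @param ... unused.
#' @return `tidy()`: one row per model term; `glance()`: a one-row model
#'   summary.
#' @export
tidy.population_slope <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope_per_frame"),
    estimate = c(x$intercept, x$slope_per_frame)
  )
}

#' @rdname tidy.population_slope
#' @export
glance.population_slope <- function(x, ...) {
  tibble::tibble(
    slope_per_frame = x$slope_per_frame,
    slope_per_hour = x$slope_per_hour,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_frames = x$n_frames,
    interval_min = x$interval_min
  )
}

#' @export
autoplot.population_slope <- function(object, ...) {
  df <- tibble::tibble(frame = seq_along(object$counts) - 1,
                       count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$count)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope_per_frame, colour = "red") +
    ggplot2::labs(x = "frame", y = "cell count",
                  title = sprintf("population slope %.3g cells/frame",
                                  object$slope_per_frame))
}
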