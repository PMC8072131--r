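#' Simulate an in vitro time-lapse movie of proliferating progenitors
#'
#' Cells are non-overlapping disks on a 2D field. Under the stochastic model
#' each cell divides with probability `p_div` and dies with probability
#' `p_death` per frame (a discrete birth-death process), so the expected
#' count follows `n0 (1 + r)^t` with `r = p_div - p_death`. The truth
#' records `expected_slope`, the least-squares slope of that expected
#' trajectory over the recorded frames -- by linearity of ordinary least
#' squares this is exactly the expectation of the fitted population slope,
#' and it reduces to the linear-regime value `n0 * r` cells/frame when
#' `frames * r` is small. The deterministic variant adds exactly
#' `add_per_frame` cells each frame. Defaults mirror a standard 4-day
#' recording: 980 frames captured every 5 minutes.
#'
#' @param n0 initial cell count.
#' @param p_div,p_death per-frame division and death probabilities in
#'   `[0, 1]`.
#' @param frames number of frames (>= 2).
#' @param interval_min capture interval in minutes.
#' @param frame_dim frame shape in pixels.
#' @param cell_radius_px disk radius in pixels.
#' @param bg,fg background/foreground intensities; `noise_sd` Gaussian noise.
#' @param add_per_frame if non-`NULL`, deterministic growth adding exactly
#'   this many cells per frame (overrides `p_div`/`p_death`).
#' @param render if `FALSE`, only the birth-death count process is
#'   simulated (no disk placement or frame images; `movie` is `NULL`), a
#'   fast path for count-level Monte-Carlo studies.
#' @param seed RNG seed.
#' @return list with `movie` (class `timelapse_movie`: `frames` list of
#'   matrices, `interval_min`) and `truth` (per-frame true counts and
#'   `expected_slope` in cells/frame).
#' @export
simulate_timelapse <- function(n0 = 100, p_div = 0.01, p_death = 0.005,
                               frames = 980, interval_min = 5,
                               frame_dim = c(256, 256), cell_radius_px = 4,
                               bg = 10, fg = 200, noise_sd = 0,
                               add_per_frame = NULL, render = TRUE,
                               seed = 1L) {
  if (frames < 2) stop("`frames` must be >= 2", call. = FALSE)
  if (any(c(p_div, p_death) < 0) || any(c(p_div, p_death) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  with_fixed_seed(seed, {
    if (!render) {
      counts <- integer(frames)
      n <- n0
      for (t in seq_len(frames)) {
        counts[t] <- n
        if (t == frames) break
        if (!is.null(add_per_frame)) {
          n <- n + add_per_frame
        } else if (n > 0) {
          n <- n + rbinom(1, n, p_div) - rbinom(1, n, p_death)
        }
      }
      return(list(
        movie = NULL,
        truth = structure(
          list(counts = counts,
               expected_slope = expected_timelapse_slope(n0, p_div, p_death,
                                                         frames,
                                                         add_per_frame)),
          class = "phantom_truth")
      ))
    }
    r <- cell_radius_px
    min_sep <- 2 * r + 2 # centres at least this far apart: disks never touch
    place <- function(centers, k) {
      # add k new non-overlapping centres; error if the field is overcrowded
      added <- 0
      tries <- 0
      while (added < k) {
        tries <- tries + 1
        if (tries > 2000 * k + 200) {
          stop("overcrowded field: cannot place all cells", call. = FALSE)
        }
        p <- c(runif(1, r + 1, frame_dim[1] - r), runif(1, r + 1, frame_dim[2] - r))
        if (nrow(centers) == 0 ||
            min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= min_sep^2) {
          centers <- rbind(centers, p)
          added <- added + 1
        }
      }
      centers
    }
    centers <- place(matrix(numeric(0), 0, 2), n0)
    counts <- integer(frames)
    frame_list <- vector("list", frames)
    render_frame <- function(centers) {
      img <- matrix(bg, frame_dim[1], frame_dim[2])
      for (ci in seq_len(nrow(centers))) {
        x0 <- centers[ci, 1]; y0 <- centers[ci, 2]
        xs <- max(1, floor(x0 - r)):min(frame_dim[1], ceiling(x0 + r))
        ys <- max(1, floor(y0 - r)):min(frame_dim[2], ceiling(y0 + r))
        d2 <- outer((xs - x0)^2, (ys - y0)^2, `+`)
        blk <- img[xs, ys]
        blk[d2 <= r^2] <- fg
        img[xs, ys] <- blk
      }
      if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
      round(pmin(pmax(img, 0), 65535))
    }
    for (t in seq_len(frames)) {
      counts[t] <- nrow(centers)
      frame_list[[t]] <- render_frame(centers)
      if (t == frames) break
      if (!is.null(add_per_frame)) {
        centers <- place(centers, add_per_frame)
      } else {
        n <- nrow(centers)
        if (n > 0) {
          births <- rbinom(1, n, p_div)
          deaths <- rbinom(1, n, p_death)
          deaths <- min(deaths, n)
          if (deaths > 0) {
            centers <- centers[-sample.int(n, deaths), , drop = FALSE]
          }
          if (births > 0) centers <- place(centers, births)
        }
      }
    }
    movie <- structure(
      list(frames = frame_list, interval_min = interval_min,
           n_frames = frames),
      class = "timelapse_movie"
    )
    truth <- structure(
      list(counts = counts,
           expected_slope = expected_timelapse_slope(n0, p_div, p_death,
                                                     frames, add_per_frame)),
      class = "phantom_truth"
    )
    list(movie = movie, truth = truth)
  })
}

# OLS slope of the exact expected trajectory n0 (1 + p_div - p_death)^t;
# equals the expectation of the fitted slope, and ~ n0 (p_div - p_death)
# when frames * (p_div - p_death) is small
expected_timelapse_slope <- function(n0, p_div, p_death, frames,
                                     add_per_frame = NULL) {
  if (!is.null(add_per_frame)) return(add_per_frame)
  t <- seq_len(frames) - 1
  expect <- n0 * (1 + p_div - p_death)^t
  sum((t - mean(t)) * (expect - mean(expect))) / sum((t - mean(t))^2)
}

#' @export
print.timelapse_movie <- function(x, ...) {
  cat(sprintf("<timelapse_movie> %d frames of %d x %d px, every %g min\n",
              x$n_frames, nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$interval_min))
  invisible(x)
}
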