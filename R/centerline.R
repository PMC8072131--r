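#' Parametric vessel centrelines
#'
#' Generates a polyline of 3D points (um) along a parametric centreline.
#' Supported kinds: `"straight"` (a segment along x), `"sine"` (a planar
#' sinusoid `y = A sin(2 pi x / lambda)`), `"helix"`
#' (`y = A cos, z = A sin`), and `"arc"` (a semicircular arc of radius
#' `length / 2` in the xy-plane, chord along x). Points are spaced so that
#' consecutive samples are at most `step` apart in arc length; the polyline
#' arc length converges to the analytic arc length as `step -> 0`.
#'
#' @param kind one of `"straight"`, `"sine"`, `"helix"`, `"arc"`.
#' @param length extent along the chord axis in um (for `"arc"`, the chord,
#'   i.e. the diameter of the semicircle).
#' @param amplitude sinusoid/helix amplitude in um (ignored for straight/arc).
#' @param wavelength sinusoid/helix wavelength in um.
#' @param step sampling step in um; must be positive and at most `length / 10`.
#' @return numeric matrix with columns `x`, `y`, `z` (um), ordered along the
#'   curve.
#' @examples
#' pl <- make_centerline("sine", length = 50, amplitude = 10, wavelength = 50)
#' centerline_tortuosity(pl)
#' @export
make_centerline <- function(kind = c("straight", "sine", "helix", "arc"),
                            length, amplitude = 0, wavelength = NULL,
                            step = min(length / 100, 0.5)) {
  kind <- match.arg(kind)
  if (!is.numeric(length) || length <= 0) {
    stop("`length` must be positive", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) {
    stop("`step` must be positive", call. = FALSE)
  }
  if (step > length / 10) {
    stop("`step` must be at most length / 10", call. = FALSE)
  }
  if (kind %in% c("sine", "helix")) {
    if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
    if (is.null(wavelength) || wavelength <= 0) {
      stop("`wavelength` must be positive for sine/helix", call. = FALSE)
    }
  }
  pts <- switch(kind,
    straight = {
      t <- seq(0, length, by = step)
      if (t[base::length(t)] < length) t <- c(t, length)
      cbind(x = t, y = 0 * t, z = 0 * t)
    },
    sine = {
      # sample x densely enough that arc steps stay below `step`
      t <- seq(0, length, length.out = max(ceiling(length / step) * 4L, 11L))
      cbind(x = t, y = amplitude * sin(2 * pi * t / wavelength), z = 0 * t)
    },
    helix = {
      t <- seq(0, length, length.out = max(ceiling(length / step) * 4L, 11L))
      w <- 2 * pi / wavelength
      cbind(x = t, y = amplitude * cos(w * t), z = amplitude * sin(w * t))
    },
    arc = {
      r <- length / 2
      nseg <- max(ceiling(pi * r / step), 10L)
      th <- seq(0, pi, length.out = nseg + 1L)
      cbind(x = r * (1 - cos(th)), y = r * sin(th), z = 0 * th)
    }
  )
  rownames(pts) <- NULL
  pts
}

#' Arc length, chord and tortuosity of a polyline
#'
#' Tortuosity is the ratio of the measured path length (the polyline arc
#' length, including all twists and turns) to the most direct path (the
#' straight-line distance between the endpoints). It is 1 for a straight
#' path and grows with curviness.
#'
#' @param polyline numeric matrix of ordered 3D points (um).
#' @return `centerline_arc_length()`: arc length in um;
#'   `centerline_tortuosity()`: dimensionless ratio `>= 1`.
#' @export
centerline_arc_length <- function(polyline) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 3, nrow(polyline) >= 2)
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' @rdname centerline_arc_length
#' @export
centerline_tortuosity <- function(polyline) {
  arc <- centerline_arc_length(polyline)
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  if (chord == 0) {
    stop("coincident endpoints: tortuosity undefined for closed curves",
         call. = FALSE)
  }
  arc / chord
}

# minimum um distance from each row of `pts` (n x 3) to a polyline
points_polyline_distance <- function(pts, polyline) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  best <- rep(Inf, n)
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  for (s in seq_len(nrow(a))) {
    ap <- sweep(pts, 2, a[s, ])
    tt <- if (len2[s] > 0) {
      pmin(1, pmax(0, as.numeric(ap %*% ab[s, ]) / len2[s]))
    } else rep(0, n)
    proj <- a[rep(s, n), , drop = FALSE] +
      matrix(tt, ncol = 1) %*% ab[s, , drop = FALSE]
    d2 <- rowSums((pts - proj)^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}
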