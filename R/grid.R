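#' Voxel grids and binary masks
#'
#' A `voxel_grid` is a 3D numeric array of intensities plus strictly positive
#' voxel spacing in micrometres and a channel label. A `voxel_mask` is the
#' logical counterpart produced by segmentation. The voxel at index
#' `(i, j, k)` (1-based) has its centre at `((i-1) dx, (j-1) dy, (k-1) dz)`
#' um; the `z = 0` face of the grid is the apical (ependymal) surface, so
#' the apical depth of a point is simply its z coordinate.
#'
#' @param data 3D numeric (or logical, for masks) array.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in um.
#' @param channel channel label, e.g. `"laminin"`.
#' @return `voxel_grid()` returns a `voxel_grid`; `voxel_mask()` a
#'   `voxel_mask` (which is also a `voxel_grid`).
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 2)), spacing = c(1, 1, 2), channel = "dapi")
#' voxel_volume(g)
#' @export
voxel_grid <- function(data, spacing, channel = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (um)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, channel = as.character(channel)[1]),
    class = "voxel_grid"
  )
}

#' @rdname voxel_grid
#' @export
voxel_mask <- function(data, spacing, channel = "mask") {
  storage.mode(data) <- "logical"
  g <- voxel_grid(data, spacing, channel)
  class(g) <- c("voxel_mask", class(g))
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (inherits(x, "voxel_mask")) "voxel_mask" else "voxel_grid"
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing (%g, %g, %g) um, channel '%s'\n",
    kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$channel
  ))
  if (inherits(x, "voxel_mask")) {
    cat(sprintf("  foreground: %d voxels (%.3g%%)\n",
                sum(x$data), 100 * mean(x$data)))
  }
  invisible(x)
}

#' @rdname voxel_grid
#' @export
voxel_volume <- function(data) {
  stopifnot(inherits(data, "voxel_grid"))
  prod(data$spacing)
}

# shared geometry check used by every mask-pair operation
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("masks must share the same grid shape", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop("masks must share the same voxel spacing", call. = FALSE)
  }
  invisible(TRUE)
}

# um coordinates of voxel centres for linear indices (1-based)
voxel_coords_um <- function(idx, dim, spacing) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(x = i * spacing[1], y = j * spacing[2], z = k * spacing[3])
}

# nearest voxel index (i, j, k, 1-based) for a point in um; NA outside grid
point_to_voxel <- function(p, dim, spacing) {
  ijk <- round(p / spacing) + 1
  if (any(ijk < 1) || any(ijk > dim)) return(rep(NA_integer_, 3))
  as.integer(ijk)
}

# run code under a fixed seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
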