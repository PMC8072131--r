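#' Euclidean distance transform in micrometres
#'
#' Anisotropy-aware exact Euclidean distance from every voxel to the nearest
#' feature voxel (voxel-centre to voxel-centre). With
#' `to = "foreground"` features are the `TRUE` voxels of the mask; with
#' `to = "background"` the `FALSE` voxels (giving the in-object depth).
#'
#' @param mask a [voxel_mask()].
#' @param to `"foreground"` or `"background"`.
#' @return numeric 3D array of distances in um (`Inf` where no feature
#'   exists).
#' @export
distance_transform <- function(mask, to = c("foreground", "background")) {
  stopifnot(inherits(mask, "voxel_mask"))
  to <- match.arg(to)
  feat <- if (to == "foreground") mask$data else !mask$data
  d2 <- edt_sq_cpp(as.logical(feat), dim(mask$data), mask$spacing)
  array(sqrt(d2), dim(mask$data))
}

# ball morphology via the distance transform
morph_ball <- function(mask, radius_um, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (radius_um <= 0) return(mask)
  if (op == "dilate") {
    d <- distance_transform(mask, "foreground")
    voxel_mask(d <= radius_um, mask$spacing, mask$channel)
  } else {
    d <- distance_transform(mask, "background")
    voxel_mask(mask$data & d > radius_um, mask$spacing, mask$channel)
  }
}

morph_open <- function(mask, radius_um) {
  morph_ball(morph_ball(mask, radius_um, "erode"), radius_um, "dilate")
}

morph_close <- function(mask, radius_um) {
  morph_ball(morph_ball(mask, radius_um, "dilate"), radius_um, "erode")
}

#' Otsu threshold of an intensity grid
#'
#' Maximizes between-class variance over a 256-bin histogram. Degenerate
#' (constant-intensity) grids raise an error rather than returning an
#' arbitrary cut.
#'
#' @param values numeric vector or array of intensities.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("degenerate histogram: constant-intensity input has no Otsu threshold",
         call. = FALSE)
  }
  nb <- 256L
  h <- tabulate(pmin(nb, floor((v - rng[1]) / diff(rng) * nb) + 1L), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  mids[which.max(sigma_b)]
}

#' Segment one intensity channel into a binary mask
#'
#' Optional Gaussian pre-smoothing (sigma in um, converted to voxels per
#' axis), thresholding (Otsu or a fixed cut; voxels strictly above the
#' threshold are foreground), then a morphological opening to remove
#' specks.
#'
#' @param grid a [voxel_grid()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required for `method = "fixed"`.
#' @param smoothing_sigma_um Gaussian sigma in um (0 = off).
#' @param opening_radius_um opening ball radius in um (0 = off).
#' @return a [voxel_mask()] with the grid's spacing and channel label.
#' @export
segment_channel <- function(grid, method = c("otsu", "fixed"),
                            threshold = NULL, smoothing_sigma_um = 0,
                            opening_radius_um = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  method <- match.arg(method)
  vals <- grid$data
  if (smoothing_sigma_um > 0) {
    sig_vox <- smoothing_sigma_um / grid$spacing
    vals <- array(gauss3d_cpp(as.numeric(vals), dim(vals), sig_vox), dim(vals))
  }
  if (method == "fixed") {
    if (is.null(threshold)) {
      stop("fixed-threshold segmentation requires `threshold`", call. = FALSE)
    }
    thr <- threshold
  } else {
    thr <- otsu_threshold(vals)
  }
  mask <- voxel_mask(vals > thr, grid$spacing, grid$channel)
  if (opening_radius_um > 0) mask <- morph_open(mask, opening_radius_um)
  mask
}

#' Total niche (V-SVZ) mask from the stained channels
#'
#' The niche volume that serves as the denominator of vessel and chain
#' densities: the union of all channel masks, morphologically closed with
#' the given ball radius, then hole-filled slice by slice. The result always
#' contains every input mask.
#'
#' @param masks list of [voxel_mask()]s sharing shape and spacing.
#' @param closing_radius_um closing ball radius in um.
#' @return a [voxel_mask()] labelled `"niche"`.
#' @export
compute_niche_mask <- function(masks, closing_radius_um = 5) {
  stopifnot(length(masks) >= 1)
  for (m in masks) stopifnot(inherits(m, "voxel_mask"))
  for (m in masks[-1]) check_same_geometry(masks[[1]], m)
  u <- Reduce(`|`, lapply(masks, function(m) m$data))
  if (!any(u)) stop("empty niche: union of channel masks is empty", call. = FALSE)
  spacing <- masks[[1]]$spacing
  closed <- morph_close(voxel_mask(u, spacing, "niche"), closing_radius_um)
  filled <- fill_holes_slicewise(closed$data)
  voxel_mask(filled | u, spacing, "niche") # closing never removes the union
}

# fill background regions not connected to the slice border, per z slice
fill_holes_slicewise <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    bg <- !sl
    lab <- array(label3d_cpp(as.logical(bg), c(d[1], d[2], 1L), 6L),
                 c(d[1], d[2]))
    border_labs <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border_labs <- border_labs[border_labs > 0]
    hole <- bg & !(lab %in% border_labs)
    out[, , k] <- sl | hole
  }
  out
}

#' Label connected components of a mask
#'
#' 6- or 26-connected components; components below `min_size` voxels are
#' discarded and the survivors are relabelled 1..n by descending voxel
#' count.
#'
#' @param mask a [voxel_mask()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @param min_size minimum voxel count to keep.
#' @return object of class `labeled_objects`: list with `labels` (integer
#'   array, 0 = background), `sizes` (tibble: `label`, `n_voxels`,
#'   `volume_um3`), `spacing`.
#' @export
label_components <- function(mask, connectivity = 26, min_size = 0) {
  stopifnot(inherits(mask, "voxel_mask"), connectivity %in% c(6, 26))
  lab <- array(label3d_cpp(as.logical(mask$data), dim(mask$data),
                           as.integer(connectivity)),
               dim(mask$data))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= max(1, min_size))
  ord <- keep[order(counts[keep], decreasing = TRUE)]
  remap <- integer(length(counts))
  remap[ord] <- seq_along(ord)
  out <- array(0L, dim(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  vx <- voxel_volume(mask)
  structure(
    list(labels = out,
         sizes = tibble::tibble(
           label = seq_along(ord),
           n_voxels = counts[ord],
           volume_um3 = counts[ord] * vx
         ),
         spacing = mask$spacing),
    class = "labeled_objects"
  )
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d objects\n", nrow(x$sizes)))
  print(utils::head(x$sizes, 10))
  invisible(x)
}
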