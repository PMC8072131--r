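#' Extract neuroblast chain objects from the DCX mask
#'
#' 26-connected components of the DCX mask above a minimum volume, with
#' um-scaled centroid, volume, 3D principal components and eccentricity per
#' object.
#'
#' @param dcx_mask a [voxel_mask()].
#' @param min_volume_um3 components below this volume are discarded.
#' @param convention passed to [chain_eccentricity()].
#' @return tibble: `chain_id`, `n_voxels`, `volume_um3`, `x_um`, `y_um`,
#'   `z_um`, `pc_max`, `pc_mid`, `pc_min`, `eccentricity`, plus a `voxels`
#'   list-column of um-scaled coordinates.
#' @export
extract_chains <- function(dcx_mask, min_volume_um3 = 20,
                           convention = c("sd", "eigenvalue")) {
  stopifnot(inherits(dcx_mask, "voxel_mask"))
  convention <- match.arg(convention)
  vx <- voxel_volume(dcx_mask)
  lab <- label_components(dcx_mask, connectivity = 26,
                          min_size = ceiling(min_volume_um3 / vx))
  rows <- purrr::map(seq_len(nrow(lab$sizes)), function(l) {
    idx <- which(lab$labels == l)
    pts <- voxel_coords_um(idx, dim(lab$labels), dcx_mask$spacing)
    pcs <- principal_components(pts, convention)
    tibble::tibble(
      chain_id = l,
      n_voxels = length(idx),
      volume_um3 = length(idx) * vx,
      x_um = mean(pts[, 1]), y_um = mean(pts[, 2]), z_um = mean(pts[, 3]),
      pc_max = pcs[1], pc_mid = pcs[2], pc_min = pcs[3],
      eccentricity = chain_eccentricity(pts, convention),
      voxels = list(pts)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chain_id = integer(), n_voxels = integer(),
                          volume_um3 = double(), x_um = double(),
                          y_um = double(), z_um = double(), pc_max = double(),
                          pc_mid = double(), pc_min = double(),
                          eccentricity = double(), voxels = list())
  }
  out
}

#' Principal components of a 3D point cloud
#'
#' Eigen-decomposition of the coordinate covariance. Under the `"sd"`
#' convention (default) the principal components are the square roots of
#' the eigenvalues, i.e. the standard deviations along the principal axes,
#' so a solid ellipsoid with semi-axes a >= b >= c has component ratio
#' b/a. The `"eigenvalue"` convention returns the raw eigenvalues; both
#' agree exactly on the line (ratio 0) and circle (ratio 1) anchor shapes.
#'
#' @param pts n x 3 matrix of um coordinates.
#' @param convention `"sd"` or `"eigenvalue"`.
#' @return numeric length-3, sorted descending.
#' @export
principal_components <- function(pts, convention = c("sd", "eigenvalue")) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  if (nrow(pts) < 2) return(c(0, 0, 0))
  ev <- eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  # eigenvalues that are pure rounding noise are exact zeros (a degenerate
  # axis), so the sqrt convention cannot inflate them to ~1e-8
  ev[ev < 1e-12 * ev[1]] <- 0
  if (convention == "sd") sqrt(ev) else ev
}

#' 3D eccentricity of a chain object
#'
#' One minus the ratio between the middle and the maximal principal
#' component of the object's point cloud: 1 indicates a line (middle
#' component 0), 0 indicates a circle or sphere (middle equals maximal).
#' Lower values mean less linear, more disorganized chains. Invariant under
#' rigid rotation, translation and uniform scaling.
#'
#' @param pts n x 3 matrix of um coordinates (or a data frame with columns
#'   x, y, z).
#' @param convention `"sd"` (component = standard deviation along the axis;
#'   default) or `"eigenvalue"` (raw covariance eigenvalue). The choice
#'   only affects intermediate shapes, not the line/circle anchors.
#' @return eccentricity in `[0, 1]`, or `NA` when all points coincide (the
#'   maximal component is 0 and the ratio is undefined).
#' @export
chain_eccentricity <- function(pts, convention = c("sd", "eigenvalue")) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  pcs <- principal_components(pts, convention)
  if (pcs[1] <= 0) return(NA_real_)
  min(max(1 - pcs[2] / pcs[1], 0), 1)
}

#' Neuroblast chain volume density
#'
#' DCX voxels divided by total niche voxels, optionally restricted to a
#' region of interest: `|DCX & ROI| / |niche & ROI|`.
#'
#' @param dcx_mask,niche_mask [voxel_mask()]s sharing geometry.
#' @param roi_mask optional ROI [voxel_mask()] (e.g. the anterior region).
#' @return scalar fraction in `[0, 1]`.
#' @export
chain_density <- function(dcx_mask, niche_mask, roi_mask = NULL) {
  check_same_geometry(dcx_mask, niche_mask)
  dcx <- dcx_mask$data
  niche <- niche_mask$data
  if (!is.null(roi_mask)) {
    check_same_geometry(dcx_mask, roi_mask)
    dcx <- dcx & roi_mask$data
    niche <- niche & roi_mask$data
  }
  denom <- sum(niche)
  if (denom == 0) stop("empty niche within the ROI", call. = FALSE)
  sum(dcx) / denom
}
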