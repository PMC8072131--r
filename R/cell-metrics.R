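#' Detect nuclei in the DAPI mask
#'
#' Connected components of the nuclear mask within a volume window become
#' cell records; the centroid is the um-scaled voxel mean and the apical
#' depth is the centroid's distance from the ependymal surface (the z = 0
#' face, or a user-supplied surface mask).
#'
#' @param dapi_mask a [voxel_mask()].
#' @param min_volume_um3,max_volume_um3 nucleus volume window.
#' @param surface_mask optional [voxel_mask()] of the ependymal surface; when
#'   given, apical depth is the um distance to it instead of the z
#'   coordinate.
#' @return tibble of cell records: `cell_id`, `n_voxels`, `volume_um3`,
#'   `x_um`, `y_um`, `z_um`, `apical_depth_um`, plus a `voxels` list-column
#'   of linear voxel indices.
#' @export
detect_nuclei <- function(dapi_mask, min_volume_um3 = 10,
                          max_volume_um3 = 5000, surface_mask = NULL) {
  stopifnot(inherits(dapi_mask, "voxel_mask"))
  vx <- voxel_volume(dapi_mask)
  lab <- label_components(dapi_mask, connectivity = 26,
                          min_size = ceiling(min_volume_um3 / vx))
  depth_map <- NULL
  if (!is.null(surface_mask)) {
    check_same_geometry(dapi_mask, surface_mask)
    depth_map <- distance_transform(surface_mask, "foreground")
  }
  rows <- purrr::map(seq_len(nrow(lab$sizes)), function(l) {
    if (lab$sizes$volume_um3[l] > max_volume_um3) return(NULL)
    idx <- which(lab$labels == l)
    pts <- voxel_coords_um(idx, dim(lab$labels), dapi_mask$spacing)
    ctr <- colMeans(pts)
    depth <- if (is.null(depth_map)) {
      ctr[3]
    } else {
      vox <- point_to_voxel(ctr, dim(lab$labels), dapi_mask$spacing)
      depth_map[vox[1], vox[2], vox[3]]
    }
    tibble::tibble(
      cell_id = l, n_voxels = length(idx),
      volume_um3 = length(idx) * vx,
      x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
      apical_depth_um = depth,
      voxels = list(idx)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cell_id = integer(), n_voxels = integer(),
                          volume_um3 = double(), x_um = double(),
                          y_um = double(), z_um = double(),
                          apical_depth_um = double(), voxels = list())
  }
  out
}

#' Classify GFAP positivity by nucleus overlap
#'
#' A cell is GFAP+ when the fraction of its nucleus voxels covered by the
#' GFAP mask reaches `overlap_threshold` (boundary inclusive). Raising the
#' threshold never adds positives.
#'
#' @param cells tibble from [detect_nuclei()].
#' @param gfap_mask a [voxel_mask()] in the same geometry as the nuclei.
#' @param overlap_threshold minimum overlap fraction in `[0, 1]`.
#' @return `cells` with columns `gfap_overlap` and `gfap_pos` added.
#' @export
classify_gfap <- function(cells, gfap_mask, overlap_threshold = 0.3) {
  stopifnot(inherits(gfap_mask, "voxel_mask"))
  if (overlap_threshold < 0 || overlap_threshold > 1) {
    stop("`overlap_threshold` must lie in [0, 1]", call. = FALSE)
  }
  gf <- gfap_mask$data
  overlap <- purrr::map_dbl(cells$voxels, function(idx) mean(gf[idx]))
  dplyr::mutate(cells, gfap_overlap = overlap,
                gfap_pos = overlap >= overlap_threshold)
}

#' Classify Ki67 positivity by nucleus overlap
#'
#' @inheritParams classify_gfap
#' @param ki67_mask a [voxel_mask()].
#' @return `cells` with columns `ki67_overlap` and `ki67_pos` added.
#' @export
classify_ki67 <- function(cells, ki67_mask, overlap_threshold = 0.3) {
  stopifnot(inherits(ki67_mask, "voxel_mask"))
  ki <- ki67_mask$data
  overlap <- purrr::map_dbl(cells$voxels, function(idx) mean(ki[idx]))
  dplyr::mutate(cells, ki67_overlap = overlap,
                ki67_pos = overlap >= overlap_threshold)
}

#' Apical filter
#'
#' Keeps cells situated within `threshold_um` of the ependymal surface
#' (apical depth less than or equal to the threshold; default 5 um).
#'
#' @param cells tibble with an `apical_depth_um` column.
#' @param threshold_um apical cutoff in um, non-negative.
#' @return the apical subset of `cells` (always a subset of the input).
#' @export
filter_apical <- function(cells, threshold_um = 5) {
  if (threshold_um < 0) stop("apical threshold must be >= 0", call. = FALSE)
  dplyr::filter(cells, .data$apical_depth_um <= threshold_um)
}

#' Count marker-positive cells, optionally within an ROI
#'
#' Counts records whose marker flag is set and whose centroid lies inside
#' the ROI mask (the whole niche when no ROI is given).
#'
#' @param cells tibble of cell records with `gfap_pos` / `ki67_pos` flags.
#' @param marker `"ki67"` or `"gfap"`.
#' @param roi_mask optional [voxel_mask()].
#' @return integer count.
#' @export
count_marker <- function(cells, marker = c("ki67", "gfap"), roi_mask = NULL) {
  marker <- match.arg(marker)
  flag_col <- paste0(marker, "_pos")
  if (!flag_col %in% names(cells)) {
    stop(sprintf("cells lack a `%s` column; classify first", flag_col),
         call. = FALSE)
  }
  pos <- cells[[flag_col]]
  pos[is.na(pos)] <- FALSE
  if (!is.null(roi_mask)) {
    stopifnot(inherits(roi_mask, "voxel_mask"))
    d <- dim(roi_mask$data)
    inside <- purrr::pmap_lgl(
      list(cells$x_um, cells$y_um, cells$z_um),
      function(x, y, z) {
        vox <- point_to_voxel(c(x, y, z), d, roi_mask$spacing)
        if (anyNA(vox)) return(FALSE)
        roi_mask$data[vox[1], vox[2], vox[3]]
      }
    )
    pos <- pos & inside
  }
  sum(pos)
}
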