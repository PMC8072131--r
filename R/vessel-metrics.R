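#' Per-branch tortuosity
#'
#' Tortuosity of one skeleton branch: the measured path length (sum of
#' consecutive um-scaled steps along the centreline, including every twist
#' and turn) divided by the most direct path (the straight-line distance
#' between the branch endpoints). Always `>= 1` up to floating tolerance.
#' Closed-loop branches (coincident endpoints) have no defined tortuosity
#' and return `NA` so they are excluded from medians.
#'
#' @param path branch voxel path, n x 3 integer matrix of (i, j, k).
#' @param spacing voxel spacing in um.
#' @param smooth_window odd moving-average window applied to the centreline
#'   before measuring length (1 = raw voxel path).
#' @return dimensionless tortuosity, or `NA` for a closed loop.
#' @export
branch_tortuosity <- function(path, spacing, smooth_window = 5) {
  stopifnot(is.matrix(path), ncol(path) == 3, nrow(path) >= 2)
  pts <- sweep(path - 1, 2, spacing, `*`)
  pts <- smooth_polyline(pts, smooth_window)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord < 1e-12) return(NA_real_)
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  max(arc / chord, 1)
}

#' Per-branch diameter from the distance transform
#'
#' The local vessel radius at a skeleton voxel is the Euclidean distance
#' from that voxel to the nearest background voxel; the branch diameter is
#' the mean of twice that distance over the branch voxels. This is the
#' standard skeleton-radius estimator. Because the distance transform
#' measures to the background voxel *centre* while the mask boundary lies
#' half a voxel closer, a half-voxel surface offset (`correction_um`) is
#' subtracted from the radius by default; the corrected radius is floored
#' at half a voxel so thin structures keep a positive diameter.
#'
#' @param path branch voxel path (n x 3, in the space of `radius_map`).
#' @param radius_map um distance-to-background array from
#'   [distance_transform()].
#' @param correction_um surface offset subtracted from each radius (um);
#'   use half the voxel pitch (0 disables the correction).
#' @return mean diameter in um; `local` attribute carries per-voxel
#'   diameters for per-voxel weighting.
#' @export
branch_diameter <- function(path, radius_map, correction_um = 0) {
  r <- radius_map[path]
  if (any(r <= 0)) {
    stop("branch voxel outside the vessel mask", call. = FALSE)
  }
  d <- 2 * pmax(r - correction_um, correction_um)
  structure(mean(d), local = d)
}

#' Branch table of a skeletonized vessel mask
#'
#' The tidy per-branch surface over [skeletonize_vessels()]: one row per
#' branch with path length, chord, tortuosity, mean diameter and the
#' capillary flag (`mean_diameter_um < capillary_um`).
#'
#' @param graph a `skeleton_graph`, or a [voxel_mask()] (skeletonized with
#'   the remaining arguments).
#' @param capillary_um capillary classification cutoff in um (default 10).
#' @param ... passed to [skeletonize_vessels()] when `graph` is a mask.
#' @return tibble: `branch_id`, `n_voxels`, `path_length_um`, `chord_um`,
#'   `tortuosity`, `mean_diameter_um`, `is_capillary`, `closed`.
#' @export
vessel_branches <- function(graph, capillary_um = 10, ...) {
  if (inherits(graph, "voxel_mask")) graph <- skeletonize_vessels(graph, ...)
  stopifnot(inherits(graph, "skeleton_graph"))
  sw <- graph$smooth_window
  rows <- purrr::map(seq_along(graph$branches), function(b) {
    path <- graph$branches[[b]]
    pts <- sweep(path - 1, 2, graph$spacing, `*`)
    chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    dm <- branch_diameter(path, graph$radius_map,
                          correction_um = mean(graph$spacing) / 2)
    tibble::tibble(
      branch_id = b,
      n_voxels = nrow(path),
      path_length_um = sum(sqrt(rowSums(diff(smooth_polyline(pts, sw))^2))),
      chord_um = chord,
      tortuosity = branch_tortuosity(path, graph$spacing, sw),
      mean_diameter_um = as.numeric(dm),
      local_diameters = list(attr(dm, "local")),
      closed = graph$closed[b]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(branch_id = integer(), n_voxels = integer(),
                          path_length_um = double(), chord_um = double(),
                          tortuosity = double(), mean_diameter_um = double(),
                          local_diameters = list(), closed = logical(),
                          is_capillary = logical()))
  }
  dplyr::mutate(out, is_capillary = .data$mean_diameter_um < capillary_um)
}

#' Vessel volume density
#'
#' Fraction of the niche volume occupied by vessel voxels: vessel voxel
#' volume divided by niche voxel volume, in `[0, 1]`. Vessel voxels outside
#' the niche mask are a containment error.
#'
#' @param vessel_mask,niche_mask [voxel_mask()]s sharing geometry.
#' @return scalar fraction.
#' @export
vessel_density <- function(vessel_mask, niche_mask) {
  check_same_geometry(vessel_mask, niche_mask)
  if (any(vessel_mask$data & !niche_mask$data)) {
    stop("vessel voxels outside the niche mask", call. = FALSE)
  }
  nn <- sum(niche_mask$data)
  if (nn == 0) stop("empty niche mask", call. = FALSE)
  sum(vessel_mask$data) / nn
}

#' Empirical diameter sample for distribution comparisons
#'
#' The sample fed to the two-sample Kolmogorov-Smirnov comparison of
#' diameter distributions. `per_branch` takes one mean diameter per branch;
#' `per_voxel` repeats each branch's local skeleton-voxel diameters, so
#' long branches weigh more.
#'
#' @param branches tibble from [vessel_branches()].
#' @param weighting `"per_branch"` or `"per_voxel"`.
#' @return numeric vector of diameters in um.
#' @export
diameter_distribution <- function(branches,
                                  weighting = c("per_branch", "per_voxel")) {
  weighting <- match.arg(weighting)
  if (nrow(branches) == 0) stop("no branches", call. = FALSE)
  if (weighting == "per_branch") {
    branches$mean_diameter_um
  } else {
    unlist(branches$local_diameters, use.names = FALSE)
  }
}

#' Whole-sample vessel summary
#'
#' Median branch tortuosity (closed loops excluded), median branch
#' diameter, vessel density, branch and capillary counts: the per-sample
#' row used by the group statistics.
#'
#' @param branches tibble from [vessel_branches()].
#' @param vessel_mask,niche_mask masks for the density denominator.
#' @return one-row tibble.
#' @export
summarize_vessels <- function(branches, vessel_mask, niche_mask) {
  tibble::tibble(
    n_branches = nrow(branches),
    median_tortuosity = median(branches$tortuosity, na.rm = TRUE),
    median_diameter_um = median(branches$mean_diameter_um),
    vessel_density = vessel_density(vessel_mask, niche_mask),
    n_capillaries = sum(branches$is_capillary),
    capillary_fraction = mean(branches$is_capillary)
  )
}
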