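#' Distance map from the vessel surface
#'
#' Anisotropy-aware Euclidean distance from every voxel to the nearest
#' vessel voxel, in um. Since laminin stains the vessel surface, the vessel
#' foreground mask is the surface: the map is exactly 0 on vessel voxels,
#' non-negative everywhere, and 1-Lipschitz in um between face neighbours.
#'
#' @param vessel_mask a non-empty [voxel_mask()].
#' @return object of class `distance_map`: list with `data` (um distances),
#'   `spacing`.
#' @export
vessel_distance_map <- function(vessel_mask) {
  stopifnot(inherits(vessel_mask, "voxel_mask"))
  if (!any(vessel_mask$data)) {
    stop("empty vessel mask: distance map undefined", call. = FALSE)
  }
  structure(
    list(data = distance_transform(vessel_mask, "foreground"),
         spacing = vessel_mask$spacing),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %s voxels, range %.2f-%.2f um\n",
              paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Minimum distance from a cell to the vessel surface
#'
#' `"centroid"` mode reads the map at the voxel nearest the cell centroid;
#' `"surface"` mode takes the minimum over the cell's boundary voxels
#' (foreground voxels of the nucleus with at least one 6-neighbour outside
#' it). Surface-mode distance never exceeds centroid-mode distance.
#'
#' @param cell one-row tibble from [detect_nuclei()] (needs `x_um`, `y_um`,
#'   `z_um` and, for surface mode, the `voxels` list-column).
#' @param map a `distance_map` from [vessel_distance_map()].
#' @param mode `"surface"` (default) or `"centroid"`.
#' @return minimum distance in um.
#' @export
min_distance_cell <- function(cell, map, mode = c("surface", "centroid")) {
  mode <- match.arg(mode)
  d <- dim(map$data)
  if (mode == "centroid") {
    vox <- point_to_voxel(c(cell$x_um, cell$y_um, cell$z_um), d, map$spacing)
    if (anyNA(vox)) stop("cell centroid outside the map domain", call. = FALSE)
    map$data[vox[1], vox[2], vox[3]]
  } else {
    idx <- cell$voxels[[1]]
    surf <- surface_voxels(idx, d)
    min(map$data[surf])
  }
}

#' Minimum distance from a chain surface to the vessel surface
#'
#' Minimum of the distance map over the chain's surface voxels. A chain
#' overlapping the vessel mask yields 0 with a warning.
#'
#' @param chain one-row tibble from [extract_chains()] (uses the `voxels`
#'   um-coordinate list-column).
#' @param map a `distance_map`.
#' @return minimum surface-to-surface distance in um.
#' @export
min_distance_chain <- function(chain, map) {
  d <- dim(map$data)
  pts <- chain$voxels[[1]]
  ijk <- round(sweep(pts, 2, map$spacing, `/`)) + 1
  idx <- (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + ijk[, 1]
  surf <- surface_voxels(idx, d)
  out <- min(map$data[surf])
  if (out == 0) {
    warning("chain overlaps or touches the vessel mask; distance 0",
            call. = FALSE)
  }
  out
}

# boundary voxels of an object given by linear indices: those with at least
# one 6-neighbour outside the object
surface_voxels <- function(idx, d) {
  obj <- sort(idx)
  ijk <- arrayInd(obj, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  on_surface <- rep(FALSE, length(obj))
  for (o in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[o, 1]
    nj <- ijk[, 2] + offs[o, 2]
    nk <- ijk[, 3] + offs[o, 3]
    outside <- ni < 1 | ni > d[1] | nj < 1 | nj > d[2] | nk < 1 | nk > d[3]
    lin <- (nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni
    p <- findInterval(lin, obj)
    member <- !outside & p > 0 & obj[pmax(p, 1)] == lin
    on_surface <- on_surface | !member
  }
  obj[on_surface]
}

#' Distances for whole cell and chain tables
#'
#' Vectorized wrappers adding a `vessel_distance_um` column.
#'
#' @param cells,chains tibbles from [detect_nuclei()] / [extract_chains()].
#' @param map a `distance_map`.
#' @param mode see [min_distance_cell()].
#' @return the input tibble with `vessel_distance_um` added.
#' @export
cell_vessel_distances <- function(cells, map,
                                  mode = c("surface", "centroid")) {
  mode <- match.arg(mode)
  dd <- purrr::map_dbl(seq_len(nrow(cells)), function(r) {
    min_distance_cell(cells[r, ], map, mode)
  })
  dplyr::mutate(cells, vessel_distance_um = dd)
}

#' @rdname cell_vessel_distances
#' @export
chain_vessel_distances <- function(chains, map) {
  dd <- purrr::map_dbl(seq_len(nrow(chains)), function(r) {
    suppressWarnings(min_distance_chain(chains[r, ], map))
  })
  dplyr::mutate(chains, vessel_distance_um = dd)
}
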