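#' Read and write image stacks as multi-page TIFF with a spacing sidecar
#'
#' Stacks are interchanged as multi-page TIFF (pages = z slices) with the
#' voxel spacing in a JSON sidecar (`<stem>.json`, keys `spacing_um` and
#' `channel`) rather than embedded in TIFF tags. Intensities are stored as
#' 16-bit integers (0..65535), so integer-valued grids round-trip
#' bit-identically. Spacing is never defaulted silently: reading fails
#' unless a sidecar exists or `spacing` is given explicitly.
#'
#' @param grid a [voxel_grid()] or [voxel_mask()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @param spacing optional explicit spacing override (um) when reading.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` a
#'   [voxel_grid()] (or [voxel_mask()] for 0/255 mask files written by
#'   [write_mask()]).
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- grid$data
  if (is.logical(vals)) {
    return(write_mask(grid, path))
  }
  if (any(vals < 0) || any(vals > 65535)) {
    stop("intensities must lie in 0..65535 for 16-bit storage", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(vals)[3]), function(k) vals[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_sidecar(path, grid$spacing, grid$channel, kind = "intensity")
  invisible(path)
}

#' @rdname write_stack
#' @export
write_mask <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- grid$data != 0
  pages <- lapply(seq_len(dim(vals)[3]), function(k) vals[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  write_sidecar(path, grid$spacing, grid$channel, kind = "mask")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

write_sidecar <- function(path, spacing, channel, kind, extra = NULL) {
  meta <- c(list(spacing_um = spacing, channel = channel, kind = kind), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    stop("ragged pages: all TIFF pages must share one shape", call. = FALSE)
  }
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(spacing)) {
    if (is.null(meta$spacing_um)) {
      stop("no voxel spacing: provide `spacing` or a JSON sidecar with `spacing_um`",
           call. = FALSE)
    }
    spacing <- as.numeric(meta$spacing_um)
  }
  channel <- if (!is.null(meta$channel)) meta$channel else "unknown"
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (identical(meta$kind, "mask")) {
    voxel_mask(arr > 0.5, spacing, channel)
  } else {
    voxel_grid(round(arr * 65535), spacing, channel)
  }
}

#' Write and read per-object metric tables
#'
#' Tables are CSV with a header row and full-precision floats; a read-back
#' equals the written table. All records must share one schema.
#'
#' @param records data frame of per-object or per-sample measurements.
#' @param path CSV path.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` a tibble.
#' @export
write_metrics_table <- function(records, path) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame with a fixed schema", call. = FALSE)
  }
  bad <- vapply(records, function(col) is.list(col), TRUE)
  if (any(bad)) {
    stop("list columns cannot be serialized to CSV: ",
         paste(names(records)[bad], collapse = ", "), call. = FALSE)
  }
  # 17 significant digits guarantee a bitwise double round trip
  out <- records
  for (cn in names(out)) {
    if (is.double(out[[cn]]) && !inherits(out[[cn]], c("Date", "POSIXt"))) {
      v <- out[[cn]]
      out[[cn]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # 17-digit decimals written above round-trip bitwise
  tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                    stringsAsFactors = FALSE))
}

#' Pipeline configuration with validated defaults
#'
#' Reads a JSON key-value document and merges it over the documented
#' defaults. Unknown keys, wrong types and out-of-range values are
#' rejected. Thresholds (all overridable):
#' \describe{
#'   \item{apical_um}{apical filter: cells within this distance of the
#'     ependymal surface count as apical (default 5 um).}
#'   \item{capillary_um}{vessels below this mean diameter are capillaries
#'     (default 10 um).}
#'   \item{gfap_overlap_fraction}{minimum nucleus/GFAP overlap fraction for
#'     a GFAP+ call (default 0.3).}
#'   \item{min_vessel_voxels, min_chain_volume_um3, min_nucleus_um3,
#'     max_nucleus_um3}{object size gates.}
#'   \item{closing_radius_um}{morphological closing radius for the niche
#'     mask (default 5).}
#'   \item{smoothing_sigma_um}{Gaussian pre-smoothing for segmentation
#'     (default 0 = off).}
#'   \item{opening_radius_um}{post-threshold opening radius (default 0).}
#'   \item{connectivity}{6 or 26 (default 26).}
#'   \item{prune_factor}{spur branches shorter than `prune_factor` x local
#'     diameter are removed from skeletons (default 2).}
#'   \item{smooth_window}{centreline smoothing window in voxels (odd,
#'     default 5).}
#'   \item{eccentricity_convention}{"sd" (square roots of covariance
#'     eigenvalues; default) or "eigenvalue".}
#'   \item{cell_distance_mode}{"surface" (default) or "centroid".}
#'   \item{diameter_weighting}{"per_branch" (default) or "per_voxel".}
#'   \item{niche}{"union" (closed union of channels; default) or "full"
#'     (whole grid, the phantom-slab convention).}
#' }
#'
#' @param path JSON config path, or `NULL` for pure defaults.
#' @return named list of validated parameters.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    apical_um = 5,
    capillary_um = 10,
    gfap_overlap_fraction = 0.3,
    min_vessel_voxels = 20,
    min_chain_volume_um3 = 20,
    min_nucleus_um3 = 10,
    max_nucleus_um3 = 5000,
    closing_radius_um = 5,
    smoothing_sigma_um = 0,
    opening_radius_um = 0,
    connectivity = 26,
    prune_factor = 2,
    smooth_window = 5,
    eccentricity_convention = "sd",
    cell_distance_mode = "surface",
    diameter_weighting = "per_branch",
    niche = "union"
  )
  cfg <- defaults
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_keys <- c("apical_um", "capillary_um", "gfap_overlap_fraction",
                "min_vessel_voxels", "min_chain_volume_um3", "min_nucleus_um3",
                "max_nucleus_um3", "closing_radius_um", "smoothing_sigma_um",
                "opening_radius_um", "prune_factor", "smooth_window")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("config key `%s` must be a single non-negative number", k),
           call. = FALSE)
    }
  }
  if (cfg$gfap_overlap_fraction > 1) {
    stop("`gfap_overlap_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!cfg$connectivity %in% c(6, 26)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  if (!cfg$eccentricity_convention %in% c("sd", "eigenvalue")) {
    stop("`eccentricity_convention` must be 'sd' or 'eigenvalue'", call. = FALSE)
  }
  if (!cfg$cell_distance_mode %in% c("surface", "centroid")) {
    stop("`cell_distance_mode` must be 'surface' or 'centroid'", call. = FALSE)
  }
  if (!cfg$diameter_weighting %in% c("per_branch", "per_voxel")) {
    stop("`diameter_weighting` must be 'per_branch' or 'per_voxel'", call. = FALSE)
  }
  if (!cfg$niche %in% c("union", "full")) {
    stop("`niche` must be 'union' or 'full'", call. = FALSE)
  }
  cfg
}

#' Write and read a time-lapse movie as single-page TIFF frames
#'
#' Frames are written as `frame_0001.tif`, ... in a directory alongside a
#' `movie.json` recording the capture interval.
#'
#' @param movie a `timelapse_movie` (see [simulate_timelapse()]).
#' @param dir directory (created if missing).
#' @return `write_movie()` returns `dir` invisibly; `read_movie()` a
#'   `timelapse_movie`.
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "timelapse_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(movie$frames)) {
    tiff::writeTIFF(movie$frames[[t]] / 65535,
                    file.path(dir, sprintf("frame_%04d.tif", t)),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(
    list(interval_min = movie$interval_min, n_frames = movie$n_frames),
    file.path(dir, "movie.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) < 2) stop("a movie needs at least 2 frames", call. = FALSE)
  frames <- lapply(files, function(f) round(tiff::readTIFF(f) * 65535))
  structure(
    list(frames = frames, interval_min = meta$interval_min,
         n_frames = length(frames)),
    class = "timelapse_movie"
  )
}
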