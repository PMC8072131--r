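#' Run the full niche-quantification pipeline
#'
#' Orchestrates phantom generation (or stack loading), segmentation, vessel,
#' chain, cell and proximity metrics, and the group statistics into one
#' reproducible run. Stages execute in dependency order; every metric table,
#' the stats report and a manifest (config hash, seed, file list with md5
#' hashes, per-stage wall-clock) are written to `out_dir`. Identical config
#' and seed produce identical output hashes.
#'
#' The run is driven by a single JSON config (see [read_pipeline_config()]
#' for the analysis thresholds). The experiment layout lives under the
#' `samples` key: a list of `{id, age, sex, seed}` records; each sample is
#' generated from the shared `phantom` spec with its own seed. Real-data
#' runs replace `phantom` with per-sample stack paths under `stacks`.
#'
#' @param config either a path to a JSON file or a named list with entries
#'   `params` (threshold overrides), `samples`, and `phantom` (phantom
#'   geometry: `dim`, `spacing`, `vessels`, `cells`, `chains`, `noise_sd`).
#' @param out_dir output directory (created).
#' @param seed master seed; each sample runs at `seed + sample index` unless
#'   it carries its own.
#' @return invisibly, a list with `tables` (named tibbles), `report`
#'   (stats results) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  t_start <- proc.time()[["elapsed"]]
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- read_pipeline_config(NULL)
  overrides <- config$params %||% list()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- validate_config(utils::modifyList(defaults, overrides))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- config$samples
  if (is.null(samples)) {
    stop("pipeline stage 'setup': config has no `samples`", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  if (!"seed" %in% names(samples)) samples$seed <- seed + seq_len(nrow(samples))
  stage_times <- c()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  per_sample <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    sm <- samples[si, ]
    stage <- sprintf("sample_%s", sm$id)
    per_sample[[si]] <- timed(stage, {
      ph <- generate_niche_phantom(phantom_spec_from_config(config$phantom,
                                                           sm$seed))
      analyze_sample(ph, sm, params)
    })
  }

  tables <- list(
    vessel_branches = bind_sample_tables(per_sample, "branches"),
    vessel_summary = bind_sample_tables(per_sample, "vessel_summary"),
    chains = bind_sample_tables(per_sample, "chains"),
    cells = bind_sample_tables(per_sample, "cells"),
    sample_summary = bind_sample_tables(per_sample, "summary")
  )
  timed("write_tables", {
    for (nm in names(tables)) {
      write_metrics_table(tables[[nm]],
                          file.path(out_dir, paste0(nm, ".csv")))
    }
  })

  report <- timed("stats", {
    run_stats_battery(tables$sample_summary, tables$vessel_branches,
                      tables$chains)
  })
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    config_hash = digest_config(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("nichemorph")),
    files = tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    ),
    stage_seconds = as.list(stage_times),
    total_seconds = round(proc.time()[["elapsed"]] - t_start, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(tables = tables, report = report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phantom_spec_from_config <- function(ph, seed) {
  if (is.null(ph)) stop("config has no `phantom` block", call. = FALSE)
  phantom_spec(
    dim = ph$dim %||% c(100, 100, 40),
    spacing = ph$spacing %||% c(1, 1, 1),
    vessels = ph$vessels,
    cells = ph$cells,
    chains = ph$chains,
    noise_sd = ph$noise_sd %||% 0,
    bg = ph$bg %||% 10, fg = ph$fg %||% 200,
    seed = seed
  )
}

# one sample: segmentation -> masks -> metrics tables
analyze_sample <- function(ph, sm, params) {
  seg <- lapply(names(ph$channels), function(nm) {
    tryCatch(
      segment_channel(ph$channels[[nm]], method = "otsu",
                      smoothing_sigma_um = params$smoothing_sigma_um,
                      opening_radius_um = params$opening_radius_um),
      error = function(e) {
        stop(sprintf("segmentation stage (channel '%s'): %s", nm,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
  names(seg) <- names(ph$channels)
  if (!any(seg$laminin$data)) {
    stop("segmentation stage: empty vessel (laminin) mask", call. = FALSE)
  }
  niche <- if (params$niche == "full") {
    voxel_mask(array(TRUE, dim(seg$laminin$data)), seg$laminin$spacing,
               "niche")
  } else {
    compute_niche_mask(seg, params$closing_radius_um)
  }
  graph <- skeletonize_vessels(seg$laminin, params$prune_factor,
                               params$smooth_window)
  branches <- vessel_branches(graph, capillary_um = params$capillary_um)
  dmap <- vessel_distance_map(seg$laminin)
  chains <- extract_chains(seg$dcx, params$min_chain_volume_um3,
                           params$eccentricity_convention)
  if (nrow(chains) > 0) chains <- chain_vessel_distances(chains, dmap)
  cells <- detect_nuclei(seg$dapi, params$min_nucleus_um3,
                         params$max_nucleus_um3)
  if (nrow(cells) > 0) {
    cells <- classify_gfap(cells, seg$gfap, params$gfap_overlap_fraction)
    cells <- classify_ki67(cells, seg$ki67, params$gfap_overlap_fraction)
    cells <- cell_vessel_distances(cells, dmap, params$cell_distance_mode)
    cells$apical <- cells$apical_depth_um <= params$apical_um
  }
  apical_gfap <- if (nrow(cells) > 0) {
    sum(cells$gfap_pos & cells$apical)
  } else 0L
  summary <- tibble::tibble(
    sample_id = sm$id, age = sm$age, sex = sm$sex,
    median_tortuosity = median(branches$tortuosity, na.rm = TRUE),
    median_diameter_um = median(branches$mean_diameter_um),
    vessel_density = vessel_density(seg$laminin, niche),
    chain_density = chain_density(seg$dcx, niche),
    median_eccentricity = if (nrow(chains)) median(chains$eccentricity) else NA,
    n_ki67 = if (nrow(cells)) count_marker(cells, "ki67") else 0L,
    n_apical_gfap = apical_gfap,
    median_cell_vessel_um = if (nrow(cells)) median(cells$vessel_distance_um) else NA,
    median_chain_vessel_um = if (nrow(chains)) median(chains$vessel_distance_um) else NA
  )
  meta <- function(tb) {
    if (nrow(tb) == 0) return(tb)
    dplyr::bind_cols(tibble::tibble(sample_id = sm$id, age = sm$age,
                                    sex = sm$sex)[rep(1, nrow(tb)), ], tb)
  }
  list(
    branches = meta(dplyr::select(branches, -"local_diameters")),
    chains = meta(dplyr::select(chains, -"voxels")),
    cells = meta(dplyr::select(cells, -"voxels")),
    vessel_summary = meta(summarize_vessels(branches, seg$laminin, niche)),
    summary = summary
  )
}

bind_sample_tables <- function(per_sample, nm) {
  dplyr::bind_rows(lapply(per_sample, `[[`, nm))
}

run_stats_battery <- function(summary, branches, chains) {
  out <- list()
  two_levels <- function(col) length(unique(summary[[col]])) >= 2
  if (nrow(summary) >= 4 && two_levels("age") && two_levels("sex")) {
    for (m in c("median_tortuosity", "median_diameter_um", "vessel_density",
                "chain_density", "median_eccentricity")) {
      if (all(is.finite(summary[[m]]))) {
        # degenerate tables (e.g. a metric constant within every group, so
        # the residual SS is 0) are skipped rather than aborting the report
        res <- tryCatch(compare_groups(summary, m, posthoc = "sidak"),
                        error = function(e) NULL)
        if (!is.null(res)) out[[m]] <- res
      }
    }
  }
  # object-level pools are reported alongside per-animal summaries so the
  # unit of inference is always explicit
  if (nrow(branches) > 0 && two_levels("sex")) {
    s <- split(branches$mean_diameter_um, branches$sex)
    if (length(s) == 2) {
      ks <- ks_two_sample(s[[1]], s[[2]])
      ks$comparison <- sprintf("diameter distribution %s vs %s (object-level)",
                               names(s)[1], names(s)[2])
      ks$adjustment <- "none"
      out$diameter_distribution <- ks
    }
  }
  dplyr::bind_rows(out, .id = "metric")
}

# order-independent hash of the config document
digest_config <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}
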