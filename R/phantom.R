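#' Specify a synthetic niche phantom
#'
#' Builds the parameter object consumed by [generate_niche_phantom()]. The
#' phantom emulates a slab of the V-SVZ niche: a tubular vessel plexus with
#' controllable centreline tortuosity and radii (laminin channel), nucleus
#' spheres with optional GFAP halos and Ki67 positivity placed at known
#' apical depths and known distances from the vessels (DAPI/GFAP/Ki67
#' channels), and elongated ellipsoidal neuroblast chains with known
#' principal-axis ratios (DCX channel). Every placed object is recorded in
#' an analytic ground-truth table, so downstream estimators can be validated
#' by parameter recovery.
#'
#' @param dim integer length-3, grid shape `(nx, ny, nz)` in voxels.
#' @param spacing numeric length-3, voxel spacing in um.
#' @param vessels data frame with one row per vessel: columns `kind`
#'   (straight/sine/helix/arc), `radius_um`, and optionally `amplitude_um`,
#'   `wavelength_um`, `y_um`, `z_um` (tube axis offset; defaults spread
#'   vessels across y at mid-depth).
#' @param cells data frame with one row per cell group: columns `n`,
#'   `radius_um`, `depth_um`, `vessel_distance_um` (NA = unconstrained),
#'   `gfap`, `ki67`.
#' @param chains data frame with one row per chain: semi-axes `a_um >= b_um
#'   >= c_um`, `theta` (rotation of the major axis about z, radians), and
#'   optionally `vessel_distance_um` (NA = unconstrained placement).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param bg,fg background and foreground intensity levels (integers,
#'   0..65535).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_niche_phantom()], [simulate_timelapse()]
#' @export
phantom_spec <- function(dim = c(100, 100, 40),
                         spacing = c(1, 1, 1),
                         vessels = NULL,
                         cells = NULL,
                         chains = NULL,
                         noise_sd = 0,
                         bg = 10, fg = 200,
                         seed = 1L) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 4L)) {
    stop("`dim` must be three voxel counts >= 4", call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive um values", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(vessels)) {
    vessels <- tibble::as_tibble(vessels)
    if (any(vessels$radius_um < min(spacing))) {
      stop("vessel radii must be at least one voxel in the finest spacing",
           call. = FALSE)
    }
  }
  structure(
    list(dim = dim, spacing = spacing,
         vessels = vessels, cells = if (!is.null(cells)) tibble::as_tibble(cells),
         chains = if (!is.null(chains)) tibble::as_tibble(chains),
         noise_sd = noise_sd, bg = bg, fg = fg, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# exact tube rasterization: voxel centre within `radius` um of the polyline,
# computed per segment on local bounding blocks
rasterize_tube <- function(dim, spacing, polyline, radius) {
  mask <- array(FALSE, dim)
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  for (s in seq_len(nrow(a))) {
    lo <- pmin(a[s, ], b[s, ]) - radius
    hi <- pmax(a[s, ], b[s, ]) + radius
    i0 <- pmax(1L, floor(lo / spacing) + 1L)
    i1 <- pmin(dim, ceiling(hi / spacing) + 1L)
    if (any(i0 > i1)) next
    xs <- (seq.int(i0[1], i1[1]) - 1) * spacing[1]
    ys <- (seq.int(i0[2], i1[2]) - 1) * spacing[2]
    zs <- (seq.int(i0[3], i1[3]) - 1) * spacing[3]
    pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    ab <- b[s, ] - a[s, ]
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a[s, ])
    tt <- if (len2 > 0) pmin(1, pmax(0, as.numeric(ap %*% ab) / len2)) else rep(0, nrow(pts))
    proj <- matrix(a[s, ], nrow(pts), 3, byrow = TRUE) + matrix(tt, ncol = 1) %*% matrix(ab, 1)
    inside <- rowSums((pts - proj)^2) <= radius^2
    if (any(inside)) {
      idx <- as.matrix(expand.grid(i = seq.int(i0[1], i1[1]),
                                   j = seq.int(i0[2], i1[2]),
                                   k = seq.int(i0[3], i1[3])))[inside, , drop = FALSE]
      mask[idx] <- TRUE
    }
  }
  mask
}

# sphere rasterization at centre (um), radius um
rasterize_sphere <- function(mask, spacing, center, radius, shell = 0) {
  dim <- dim(mask)
  r_out <- radius + shell
  i0 <- pmax(1L, floor((center - r_out) / spacing) + 1L)
  i1 <- pmin(dim, ceiling((center + r_out) / spacing) + 1L)
  xs <- (seq.int(i0[1], i1[1]) - 1) * spacing[1] - center[1]
  ys <- (seq.int(i0[2], i1[2]) - 1) * spacing[2] - center[2]
  zs <- (seq.int(i0[3], i1[3]) - 1) * spacing[3] - center[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  sel <- if (shell > 0) d2 <= r_out^2 & d2 >= radius^2 else d2 <= radius^2
  blk <- mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3]), drop = FALSE]
  mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3])] <- blk | sel
  mask
}

# ellipsoid with semi-axes (a, b, c) um, major axis rotated by theta about z
rasterize_ellipsoid <- function(mask, spacing, center, axes, theta) {
  dim <- dim(mask)
  rmax <- max(axes)
  i0 <- pmax(1L, floor((center - rmax) / spacing) + 1L)
  i1 <- pmin(dim, ceiling((center + rmax) / spacing) + 1L)
  xs <- (seq.int(i0[1], i1[1]) - 1) * spacing[1] - center[1]
  ys <- (seq.int(i0[2], i1[2]) - 1) * spacing[2] - center[2]
  zs <- (seq.int(i0[3], i1[3]) - 1) * spacing[3] - center[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  u <- (cos(theta) * g$x + sin(theta) * g$y) / axes[1]
  v <- (-sin(theta) * g$x + cos(theta) * g$y) / axes[2]
  w <- g$z / axes[3]
  sel <- array(u^2 + v^2 + w^2 <= 1, dim = c(length(xs), length(ys), length(zs)))
  blk <- mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3]), drop = FALSE]
  mask[seq.int(i0[1], i1[1]), seq.int(i0[2], i1[2]), seq.int(i0[3], i1[3])] <- blk | sel
  mask
}

#' Generate a synthetic niche phantom with analytic ground truth
#'
#' Rasterizes the objects described by a [phantom_spec()] into five intensity
#' channels (laminin, dcx, gfap, ki67, dapi) and returns them together with
#' the ground truth: per-vessel analytic tortuosity and radius, the analytic
#' vessel volume fraction, per-cell true depth and true minimum distance to
#' the vessel surface, and per-chain principal-component ratio. A voxel is
#' foreground iff its centre lies inside the object (no antialiasing), so
#' voxel-counted volumes match analytic volumes to voxelization tolerance.
#'
#' @param spec a [phantom_spec()].
#' @return list with `channels` (named list of [voxel_grid()]), `masks`
#'   (named list of the noiseless truth [voxel_mask()]s) and `truth` (class
#'   `phantom_truth`: tibbles `vessels`, `cells`, `chains` plus
#'   `vessel_volume_fraction` and `chain_volume_fraction`).
#' @export
generate_niche_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_fixed_seed(spec$seed, {
    dim <- spec$dim
    spacing <- spec$spacing
    ext <- (dim - 1) * spacing # um extent of voxel-centre lattice
    total_um3 <- prod(dim) * prod(spacing)

    lam <- array(FALSE, dim)
    dcx <- array(FALSE, dim)
    gfap <- array(FALSE, dim)
    ki67 <- array(FALSE, dim)
    dapi <- array(FALSE, dim)

    # ---- vessels ----
    polylines <- list()
    vtruth <- NULL
    if (!is.null(spec$vessels) && nrow(spec$vessels) > 0) {
      nv <- nrow(spec$vessels)
      vs <- spec$vessels
      # default axes snap to the voxel-centre lattice: a tube axis midway
      # between voxel centres suffers the worst-case voxelization error of
      # the cross-section, which would violate the 10% volume tolerance for
      # thin tubes
      snap <- function(v, sp) round(v / sp) * sp
      if (!"y_um" %in% names(vs)) {
        vs$y_um <- snap(ext[2] * seq_len(nv) / (nv + 1), spacing[2])
      }
      if (!"z_um" %in% names(vs)) {
        vs$z_um <- rep(snap(ext[3] * 0.6, spacing[3]), nv)
      }
      if (!"amplitude_um" %in% names(vs)) vs$amplitude_um <- rep(0, nv)
      if (!"wavelength_um" %in% names(vs)) vs$wavelength_um <- rep(ext[1], nv)
      rows <- vector("list", nv)
      for (v in seq_len(nv)) {
        pl <- make_centerline(vs$kind[v], length = ext[1],
                              amplitude = vs$amplitude_um[v],
                              wavelength = vs$wavelength_um[v],
                              step = min(spacing) / 2)
        pl[, 2] <- pl[, 2] + vs$y_um[v]
        pl[, 3] <- pl[, 3] + vs$z_um[v]
        lam <- lam | rasterize_tube(dim, spacing, pl, vs$radius_um[v])
        polylines[[v]] <- pl
        rows[[v]] <- tibble::tibble(
          vessel_id = v, kind = vs$kind[v], radius_um = vs$radius_um[v],
          arc_length_um = centerline_arc_length(pl),
          tortuosity = centerline_tortuosity(pl)
        )
      }
      vtruth <- dplyr::bind_rows(rows)
    }
    vessel_fraction <- if (is.null(vtruth)) 0 else {
      sum(pi * vtruth$radius_um^2 * vtruth$arc_length_um) / total_um3
    }

    # analytic distance from points to the nearest vessel *surface*
    surface_distance <- function(pts) {
      if (length(polylines) == 0) return(rep(Inf, nrow(pts)))
      d <- rep(Inf, nrow(pts))
      for (v in seq_along(polylines)) {
        d <- pmin(d, points_polyline_distance(pts, polylines[[v]]) -
                       spec$vessels$radius_um[v])
      }
      d
    }

    # ---- cells ----
    ctruth <- NULL
    if (!is.null(spec$cells) && nrow(spec$cells) > 0) {
      cells_spec <- spec$cells
      if (!"depth_um" %in% names(cells_spec)) cells_spec$depth_um <- NA_real_
      if (!"vessel_distance_um" %in% names(cells_spec)) {
        cells_spec$vessel_distance_um <- NA_real_
      }
      if (!"gfap" %in% names(cells_spec)) cells_spec$gfap <- FALSE
      if (!"ki67" %in% names(cells_spec)) cells_spec$ki67 <- FALSE
      placed <- list()
      centers <- matrix(numeric(0), 0, 3)
      radii <- numeric(0)
      cid <- 0
      for (gidx in seq_len(nrow(cells_spec))) {
        cs <- cells_spec[gidx, ]
        for (rep_i in seq_len(cs$n)) {
          cid <- cid + 1
          ctr <- unname(place_cell(cs, polylines, spec, ext, centers,
                                   radii))
          if (is.null(ctr)) {
            stop(sprintf(
              "cell group %d: cannot place a cell at depth %g um / vessel distance %g um inside the grid",
              gidx, cs$depth_um, cs$vessel_distance_um), call. = FALSE)
          }
          centers <- rbind(centers, ctr)
          radii <- c(radii, cs$radius_um)
          dapi <- rasterize_sphere(dapi, spacing, ctr, cs$radius_um)
          if (isTRUE(cs$gfap)) {
            gfap <- rasterize_sphere(gfap, spacing, ctr, cs$radius_um + 1.5)
          }
          if (isTRUE(cs$ki67)) {
            ki67 <- rasterize_sphere(ki67, spacing, ctr, cs$radius_um)
          }
          placed[[cid]] <- tibble::tibble(
            cell_id = cid, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
            radius_um = cs$radius_um, depth_um = ctr[3],
            vessel_distance_um = surface_distance(matrix(ctr, 1)),
            gfap = isTRUE(cs$gfap), ki67 = isTRUE(cs$ki67)
          )
        }
      }
      ctruth <- dplyr::bind_rows(placed)
    }

    # ---- chains ----
    htruth <- NULL
    chain_volume <- 0
    if (!is.null(spec$chains) && nrow(spec$chains) > 0) {
      ch <- spec$chains
      if (!"theta" %in% names(ch)) ch$theta <- rep(0, nrow(ch))
      if (!"vessel_distance_um" %in% names(ch)) {
        ch$vessel_distance_um <- rep(NA_real_, nrow(ch))
      }
      rows <- vector("list", nrow(ch))
      ch_centers <- matrix(numeric(0), 0, 3)
      ch_reach <- numeric(0)
      for (ci in seq_len(nrow(ch))) {
        axes <- c(ch$a_um[ci], ch$b_um[ci], ch$c_um[ci])
        ctr <- unname(place_chain(ch[ci, ], axes, polylines, spec, ext,
                                  ch_centers, ch_reach))
        ch_centers <- rbind(ch_centers, ctr)
        ch_reach <- c(ch_reach, max(axes))
        if (is.null(ctr)) {
          stop(sprintf("chain %d does not fit the grid", ci), call. = FALSE)
        }
        dcx <- rasterize_ellipsoid(dcx, spacing, ctr, axes, ch$theta[ci])
        chain_volume <- chain_volume + 4 / 3 * pi * prod(axes)
        rows[[ci]] <- tibble::tibble(
          chain_id = ci, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
          a_um = axes[1], b_um = axes[2], c_um = axes[3],
          theta = ch$theta[ci],
          volume_um3 = 4 / 3 * pi * prod(axes),
          pc_ratio = axes[2] / axes[1],
          eccentricity = 1 - axes[2] / axes[1],
          vessel_distance_um = ch$vessel_distance_um[ci]
        )
      }
      htruth <- dplyr::bind_rows(rows)
    }

    # ---- intensities ----
    as_channel <- function(mask, label) {
      img <- array(spec$bg, dim)
      img[mask] <- spec$fg
      if (spec$noise_sd > 0) {
        img <- img + rnorm(length(img), 0, spec$noise_sd)
      }
      img <- round(pmin(pmax(img, 0), 65535))
      voxel_grid(img, spacing, label)
    }
    channels <- list(
      laminin = as_channel(lam, "laminin"),
      dcx = as_channel(dcx, "dcx"),
      gfap = as_channel(gfap, "gfap"),
      ki67 = as_channel(ki67, "ki67"),
      dapi = as_channel(dapi, "dapi")
    )
    masks <- list(
      laminin = voxel_mask(lam, spacing, "laminin"),
      dcx = voxel_mask(dcx, spacing, "dcx"),
      gfap = voxel_mask(gfap, spacing, "gfap"),
      ki67 = voxel_mask(ki67, spacing, "ki67"),
      dapi = voxel_mask(dapi, spacing, "dapi")
    )
    truth <- structure(
      list(vessels = vtruth, cells = ctruth, chains = htruth,
           vessel_volume_fraction = vessel_fraction,
           chain_volume_fraction = chain_volume / total_um3,
           dim = dim, spacing = spacing),
      class = "phantom_truth"
    )
    list(channels = channels, masks = masks, truth = truth)
  })
}

# choose a cell centre honouring depth and vessel-surface distance
place_cell <- function(cs, polylines, spec, ext, centers, radii) {
  margin <- cs$radius_um + 1
  d_req <- cs$vessel_distance_um
  # nuclei must stay disjoint (26-connectivity would merge touching blobs)
  sep_ok <- function(ctr) {
    nrow(centers) == 0 ||
      min(sqrt(rowSums(sweep(centers, 2, ctr)^2)) - radii) >
        cs$radius_um + 2 * max(spec$spacing)
  }
  for (attempt in 1:500) {
    if (!is.na(d_req) && length(polylines) > 0) {
      v <- sample.int(length(polylines), 1)
      pl <- polylines[[v]]
      r <- spec$vessels$radius_um[v]
      # random point along the tube, away from the ends
      arc <- cumsum(c(0, sqrt(rowSums(diff(pl)^2))))
      smax <- arc[length(arc)]
      s <- runif(1, 0.15 * smax, 0.85 * smax)
      i <- findInterval(s, arc)
      p0 <- pl[i, ]
      z_tgt <- if (is.na(cs$depth_um)) p0[3] else cs$depth_um
      dz <- z_tgt - p0[3]
      reach <- r + d_req
      if (abs(dz) > reach) next
      dy <- sqrt(reach^2 - dz^2) * sample(c(-1, 1), 1)
      ctr <- c(p0[1], p0[2] + dy, z_tgt)
    } else {
      z_tgt <- if (is.na(cs$depth_um)) runif(1, margin, ext[3] - margin) else cs$depth_um
      ctr <- c(runif(1, margin, ext[1] - margin),
               runif(1, margin, ext[2] - margin), z_tgt)
    }
    if (any(ctr < c(margin, margin, 0)) || any(ctr > ext - c(margin, margin, 0))) next
    if (ctr[3] > ext[3]) next
    if (!sep_ok(ctr)) next
    return(ctr)
  }
  NULL
}

# choose a chain centre; if a vessel distance is requested the chain is
# offset along y from a random point of a random vessel so that the gap
# between the ellipsoid support surface and the tube surface equals it
place_chain <- function(ch, axes, polylines, spec, ext, centers, reach) {
  sep_ok <- function(ctr) {
    nrow(centers) == 0 ||
      min(sqrt(rowSums(sweep(centers, 2, ctr)^2)) - reach) >
        max(axes) + 2 * max(spec$spacing)
  }
  for (attempt in 1:500) {
    if (!is.na(ch$vessel_distance_um) && length(polylines) > 0) {
      v <- sample.int(length(polylines), 1)
      pl <- polylines[[v]]
      r <- spec$vessels$radius_um[v]
      arc <- cumsum(c(0, sqrt(rowSums(diff(pl)^2))))
      s <- runif(1, 0.2 * arc[length(arc)], 0.8 * arc[length(arc)])
      i <- findInterval(s, arc)
      p0 <- pl[i, ]
      supp_y <- sqrt((axes[1] * sin(ch$theta))^2 + (axes[2] * cos(ch$theta))^2)
      dy <- (r + ch$vessel_distance_um + supp_y) * sample(c(-1, 1), 1)
      ctr <- c(p0[1], p0[2] + dy, p0[3])
    } else {
      ctr <- c(runif(1, axes[1], ext[1] - axes[1]),
               runif(1, axes[1], ext[2] - axes[1]),
               runif(1, axes[3], ext[3] - axes[3]))
    }
    lo <- ctr - c(max(axes), max(axes), axes[3])
    hi <- ctr + c(max(axes), max(axes), axes[3])
    if (all(lo >= 0) && all(hi <= ext) && sep_ok(ctr)) return(ctr)
  }
  NULL
}
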