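#' Skeletonize a vessel mask into a branch graph
#'
#' Topology-preserving 3D curve thinning of the vessel mask, followed by
#' graph decomposition: junctions and endpoints become nodes, the ordered
#' 26-connected voxel paths between them become branches. Spur branches
#' shorter than `prune_factor` times their local diameter (thinning
#' artifacts that inflate tortuosity) are removed, then degree-2 nodes are
#' merged. Anisotropic masks are resampled to isotropic spacing (the finest
#' axis) by trilinear interpolation before thinning; all reported lengths
#' are in um regardless.
#'
#' @param mask a [voxel_mask()] of the vessel (laminin) channel.
#' @param prune_factor spur-prune length as a multiple of the local mean
#'   diameter (default 2).
#' @param smooth_window odd moving-average window (voxels) applied to branch
#'   centrelines before measuring path length; counters the digital
#'   overestimate of arc length (default 5; 1 = off).
#' @return object of class `skeleton_graph`: `skeleton` ([voxel_mask()] in
#'   the (possibly resampled) isotropic space), `branches` (list of voxel
#'   index paths, n x 3), `nodes` (tibble), `spacing`, and `radius_map`
#'   (um distance to background, for diameters).
#' @export
skeletonize_vessels <- function(mask, prune_factor = 2, smooth_window = 5) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$data)) stop("empty vessel mask", call. = FALSE)
  if (max(mask$spacing) / min(mask$spacing) > 1 + 1e-9) {
    mask <- resample_isotropic(mask)
  }
  spacing <- mask$spacing
  skel <- array(thin3d_cpp(as.logical(mask$data), dim(mask$data)),
                dim(mask$data))
  rmap <- distance_transform(mask, "background")
  for (iter in 1:5) {
    g <- skeleton_to_graph(skel, spacing)
    spur <- find_spurs(g, rmap, prune_factor, spacing)
    if (length(spur) == 0) break
    for (b in spur) {
      path <- g$branches[[b]]
      ends <- g$branch_ends[[b]]
      keep <- logical(nrow(path))
      # keep any endpoint that is a junction (degree >= 3)
      if (g$nodes$degree[ends[1]] >= 3) keep[1] <- TRUE
      if (g$nodes$degree[ends[2]] >= 3) keep[nrow(path)] <- TRUE
      skel[path[!keep, , drop = FALSE]] <- FALSE
    }
  }
  g <- skeleton_to_graph(skel, spacing)
  structure(
    list(skeleton = voxel_mask(skel, spacing, "skeleton"),
         branches = g$branches, branch_ends = g$branch_ends,
         closed = g$closed, nodes = g$nodes, spacing = spacing,
         radius_map = rmap, smooth_window = smooth_window),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d branches, spacing %g um\n",
              nrow(x$nodes), length(x$branches), x$spacing[1]))
  invisible(x)
}

# trilinear resampling of a mask to isotropic spacing (finest axis)
resample_isotropic <- function(mask) {
  s <- mask$spacing
  iso <- min(s)
  d <- dim(mask$data)
  ext <- (d - 1) * s
  nd <- pmax(2L, as.integer(floor(ext / iso)) + 1L)
  xs <- (seq_len(nd[1]) - 1) * iso / s[1] # fractional source indices (0-based)
  ys <- (seq_len(nd[2]) - 1) * iso / s[2]
  zs <- (seq_len(nd[3]) - 1) * iso / s[3]
  src <- mask$data * 1.0
  out <- array(0, nd)
  x0 <- pmin(floor(xs), d[1] - 2); fx <- xs - x0
  y0 <- pmin(floor(ys), d[2] - 2); fy <- ys - y0
  z0 <- pmin(floor(zs), d[3] - 2); fz <- zs - z0
  for (k in seq_len(nd[3])) {
    za <- src[, , z0[k] + 1]; zb <- src[, , z0[k] + 2]
    sl <- za * (1 - fz[k]) + zb * fz[k]
    # interpolate rows then columns
    ra <- sl[x0 + 1, , drop = FALSE] * (1 - fx) + sl[x0 + 2, , drop = FALSE] * fx
    out[, , k] <- ra[, y0 + 1, drop = FALSE] * (1 - fy)[col(matrix(0, nd[1], nd[2]))] +
      ra[, y0 + 2, drop = FALSE] * fy[col(matrix(0, nd[1], nd[2]))]
  }
  voxel_mask(out >= 0.5, rep(iso, 3), mask$channel)
}

# decompose a skeleton voxel array into nodes and ordered branch paths
skeleton_to_graph <- function(skel, spacing) {
  d <- dim(skel)
  idx <- which(skel)
  n <- length(idx)
  nodes_empty <- tibble::tibble(node_id = integer(), i = integer(),
                                j = integer(), k = integer(),
                                degree = integer())
  if (n == 0) {
    return(list(branches = list(), branch_ends = list(), closed = logical(),
                nodes = nodes_empty))
  }
  ijk <- arrayInd(idx, d)
  # adjacency among skeleton voxels, 26-connectivity
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", n)
  pos_of <- integer(0)
  ord <- order(idx)
  sorted_idx <- idx[ord]
  lookup <- function(lin) {
    p <- findInterval(lin, sorted_idx)
    hit <- p > 0 & sorted_idx[pmax(p, 1)] == lin
    out <- rep(NA_integer_, length(lin))
    out[hit] <- ord[p[hit]]
    out
  }
  for (o in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[o, 1]
    nj <- ijk[, 2] + offs[o, 2]
    nk <- ijk[, 3] + offs[o, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    lin <- (nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni
    hit <- lookup(ifelse(ok, lin, 0))
    for (v in which(!is.na(hit))) adj[[v]] <- c(adj[[v]], hit[v])
  }
  deg <- lengths(adj)
  is_node <- deg != 2L
  node_pos <- which(is_node)
  branches <- list()
  branch_ends <- list()
  closed <- logical()
  visited_step <- new.env(hash = TRUE)
  step_key <- function(a, b) paste0(a, "_", b)
  node_id_of <- integer(n)
  node_id_of[node_pos] <- seq_along(node_pos)
  for (v in node_pos) {
    for (nb in adj[[v]]) {
      key <- step_key(v, nb)
      if (!is.null(visited_step[[key]])) next
      path <- c(v, nb)
      prev <- v
      cur <- nb
      while (!is_node[cur]) {
        nxt <- adj[[cur]][adj[[cur]] != prev][1]
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      visited_step[[key]] <- TRUE
      visited_step[[step_key(cur, prev)]] <- TRUE
      if (length(path) >= 2) {
        branches[[length(branches) + 1]] <- ijk[path, , drop = FALSE]
        branch_ends[[length(branch_ends) + 1]] <-
          c(node_id_of[path[1]], node_id_of[path[length(path)]])
        closed <- c(closed, path[1] == path[length(path)])
      }
    }
  }
  # pure cycles (components with no node voxel)
  in_branch <- new.env(hash = TRUE)
  for (b in branches) for (r in seq_len(nrow(b))) {
    in_branch[[paste(b[r, ], collapse = "_")]] <- TRUE
  }
  seen <- vapply(seq_len(n), function(v) {
    !is.null(in_branch[[paste(ijk[v, ], collapse = "_")]])
  }, TRUE)
  for (v in which(deg == 2L & !seen)) {
    if (seen[v]) next
    path <- v
    prev <- v
    cur <- adj[[v]][1]
    while (cur != v) {
      path <- c(path, cur)
      nxt <- adj[[cur]][adj[[cur]] != prev][1]
      prev <- cur
      cur <- nxt
    }
    path <- c(path, v)
    seen[path] <- TRUE
    branches[[length(branches) + 1]] <- ijk[path, , drop = FALSE]
    branch_ends[[length(branch_ends) + 1]] <- c(NA_integer_, NA_integer_)
    closed <- c(closed, TRUE)
  }
  nodes <- tibble::tibble(
    node_id = seq_along(node_pos),
    i = ijk[node_pos, 1], j = ijk[node_pos, 2], k = ijk[node_pos, 3],
    degree = deg[node_pos]
  )
  list(branches = branches, branch_ends = branch_ends, closed = closed,
       nodes = nodes)
}

# spur = branch with exactly one degree-1 endpoint attached to a junction,
# shorter than prune_factor * its local mean diameter
find_spurs <- function(g, rmap, prune_factor, spacing) {
  if (length(g$branches) == 0) return(integer(0))
  out <- integer(0)
  for (b in seq_along(g$branches)) {
    ends <- g$branch_ends[[b]]
    if (any(is.na(ends))) next
    degs <- g$nodes$degree[ends]
    if (!(sum(degs == 1) == 1 && max(degs) >= 3)) next
    path <- g$branches[[b]]
    plen <- path_length_um(path, spacing)
    diam <- 2 * mean(rmap[path])
    if (plen < prune_factor * diam) out <- c(out, b)
  }
  out
}

path_length_um <- function(path, spacing) {
  if (nrow(path) < 2) return(0)
  steps <- diff(path)
  sum(sqrt((steps[, 1] * spacing[1])^2 + (steps[, 2] * spacing[2])^2 +
             (steps[, 3] * spacing[3])^2))
}

# moving-average smoothing of a polyline (um coordinates), endpoints fixed
smooth_polyline <- function(pts, window) {
  n <- nrow(pts)
  if (window <= 1 || n <= 2) return(pts)
  half <- floor(window / 2)
  out <- pts
  for (r in 2:(n - 1)) {
    lo <- max(1, r - half)
    hi <- min(n, r + half)
    out[r, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}
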