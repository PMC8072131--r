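test_that("the distance map is zero on vessels and exact for face neighbours", {
  m <- array(FALSE, c(10, 10, 10))
  m[5, 5, 5] <- TRUE
  map <- vessel_distance_map(voxel_mask(m, c(1, 1, 1)))
  expect_equal(map$data[5, 5, 5], 0)
  expect_equal(map$data[6, 5, 5], 1)
  expect_equal(map$data[5, 4, 5], 1)
  expect_equal(map$data[6, 6, 5], sqrt(2))
  expect_error(vessel_distance_map(voxel_mask(array(FALSE, c(4, 4, 4)),
                                              c(1, 1, 1))), "empty")
})

test_that("the distance map equals brute force on random small grids", {
  set.seed(12)
  for (rep in 1:25) {
    d <- sample(4:15, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.08, d)
    if (!any(m)) m[sample(prod(d), 1)] <- TRUE
    sp <- sample(c(1, 1, 1, 2, 0.5), 3, replace = TRUE)
    map <- vessel_distance_map(voxel_mask(m, sp))
    expect_equal(map$data, brute_force_distance(m, sp), tolerance = 1e-9)
  }
})

test_that("the map is 1-Lipschitz in um between face neighbours", {
  ph <- straight_tube_phantom(3, dim = c(40, 30, 20))
  map <- vessel_distance_map(ph$masks$laminin)
  d <- dim(map$data)
  dx <- abs(map$data[-1, , ] - map$data[-d[1], , ]) # along x, spacing 1
  dy <- abs(map$data[, -1, ] - map$data[, -d[2], ])
  expect_lte(max(dx), 1 + 1e-12)
  expect_lte(max(dy), 1 + 1e-12)
})

test_that("cell distances support centroid and surface modes coherently", {
  # flat vessel wall at x index 1; cell sphere centred 10 um away
  m <- array(FALSE, c(40, 20, 20))
  m[1, , ] <- TRUE
  map <- vessel_distance_map(voxel_mask(m, c(1, 1, 1)))
  nuc <- array(FALSE, c(40, 20, 20))
  nuc <- nichemorph:::rasterize_sphere(nuc, c(1, 1, 1), c(10, 10, 10), 3)
  cells <- detect_nuclei(voxel_mask(nuc, c(1, 1, 1)))
  d_cen <- min_distance_cell(cells[1, ], map, "centroid")
  d_surf <- min_distance_cell(cells[1, ], map, "surface")
  expect_equal(d_cen, 10, tolerance = 0.5)
  expect_equal(d_surf, 7, tolerance = 0.5)
  expect_lte(d_surf, d_cen)

  # a cell touching the vessel has surface distance 0
  nuc2 <- array(FALSE, c(40, 20, 20))
  nuc2[1:4, 8:12, 8:12] <- TRUE
  cells2 <- detect_nuclei(voxel_mask(nuc2, c(1, 1, 1)))
  expect_equal(min_distance_cell(cells2[1, ], map, "surface"), 0)
})

test_that("surface-mode distance never exceeds centroid-mode distance", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(80, 60, 30),
    vessels = data.frame(kind = "straight", radius_um = 3, y_um = 30,
                         z_um = 10),
    cells = data.frame(n = 8, radius_um = 2.5, depth_um = NA,
                       vessel_distance_um = NA, gfap = FALSE, ki67 = FALSE),
    seed = 9
  ))
  map <- vessel_distance_map(ph$masks$laminin)
  cells <- detect_nuclei(ph$masks$dapi)
  for (r in seq_len(nrow(cells))) {
    expect_lte(min_distance_cell(cells[r, ], map, "surface"),
               min_distance_cell(cells[r, ], map, "centroid") + 1e-12)
  }
})

test_that("adding vessels never increases any distance", {
  set.seed(13)
  m1 <- array(runif(8000) < 0.02, c(20, 20, 20))
  m1[3, 3, 3] <- TRUE
  extra <- array(runif(8000) < 0.02, c(20, 20, 20))
  m2 <- m1 | extra
  d1 <- vessel_distance_map(voxel_mask(m1, c(1, 1, 1)))$data
  d2 <- vessel_distance_map(voxel_mask(m2, c(1, 1, 1)))$data
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("phantom cell and chain truth distances are recovered", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(100, 80, 30),
    vessels = data.frame(kind = "straight", radius_um = 3, y_um = 40,
                         z_um = 12),
    cells = data.frame(n = c(3, 3, 3), radius_um = 2.5, depth_um = 12,
                       vessel_distance_um = c(2, 8, 15),
                       gfap = FALSE, ki67 = FALSE),
    chains = data.frame(a_um = c(9, 8), b_um = c(4, 3.5), c_um = 2,
                        theta = 0, vessel_distance_um = c(5, 10)),
    seed = 10
  ))
  map <- vessel_distance_map(ph$masks$laminin)
  voxel_diag <- sqrt(3)

  cells <- cell_vessel_distances(detect_nuclei(ph$masks$dapi), map,
                                 "centroid")
  tr <- ph$truth$cells
  match_idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((tr$x_um - cells$x_um[i])^2 + (tr$y_um - cells$y_um[i])^2 +
                (tr$z_um - cells$z_um[i])^2)
  }, 0L)
  expect_true(all(abs(cells$vessel_distance_um -
                        tr$vessel_distance_um[match_idx]) <= voxel_diag))

  chains <- chain_vessel_distances(extract_chains(ph$masks$dcx, 20), map)
  trc <- ph$truth$chains
  match_c <- vapply(seq_len(nrow(chains)), function(i) {
    which.min((trc$x_um - chains$x_um[i])^2 + (trc$y_um - chains$y_um[i])^2)
  }, 0L)
  expect_true(all(abs(chains$vessel_distance_um -
                        trc$vessel_distance_um[match_c]) <= voxel_diag))
})

test_that("a chain overlapping the vessel mask reports zero with a warning", {
  m <- array(FALSE, c(30, 20, 10))
  m[10:20, 8:12, 4:7] <- TRUE
  map <- vessel_distance_map(voxel_mask(m, c(1, 1, 1)))
  ch_mask <- array(FALSE, c(30, 20, 10))
  ch_mask[15:25, 10:14, 4:7] <- TRUE # overlaps the vessel block
  chains <- extract_chains(voxel_mask(ch_mask, c(1, 1, 1)), 1)
  expect_warning(d <- min_distance_chain(chains[1, ], map), "overlap")
  expect_equal(d, 0)
})
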