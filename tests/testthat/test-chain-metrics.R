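test_that("eccentricity anchors: a line is exactly 1, a circle exactly 0", {
  # 100 evenly spaced collinear points along an arbitrary 3D direction
  dir <- c(2, -1, 3) / sqrt(14)
  line <- outer(seq(0, 99), dir)
  expect_equal(chain_eccentricity(line), 1.0, tolerance = 1e-12)

  # points evenly spaced on a circle in a rotated plane
  circ <- circle_points(n = 360, r = 10, seed = 2)
  expect_equal(chain_eccentricity(circ), 0.0, tolerance = 1e-12)

  # both conventions agree exactly on the anchors
  expect_equal(chain_eccentricity(line, "eigenvalue"), 1.0, tolerance = 1e-12)
  expect_equal(chain_eccentricity(circ, "eigenvalue"), 0.0, tolerance = 1e-12)
})

test_that("solid-shape eccentricities follow the semi-axis ratios", {
  # rasterized ellipsoid 10 x 5 x 2 um: 1 - 5/10 = 0.5
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(60, 60, 30),
    chains = data.frame(a_um = 10, b_um = 5, c_um = 2), seed = 2
  ))
  ch <- extract_chains(ph$masks$dcx, min_volume_um3 = 20)
  expect_equal(nrow(ch), 1L)
  expect_lt(abs(ch$eccentricity - 0.5) / 0.5, 0.05)
  expect_lt(abs(ch$volume_um3 - 4 / 3 * pi * 100) / (4 / 3 * pi * 100), 0.10)

  # uniform solid sphere: 0 within 2%
  sph <- generate_niche_phantom(phantom_spec(
    dim = c(30, 30, 30),
    chains = data.frame(a_um = 8, b_um = 8, c_um = 8), seed = 3
  ))
  ch2 <- extract_chains(sph$masks$dcx, 20)
  expect_lt(ch2$eccentricity, 0.02)
})

test_that("eccentricity is invariant under rigid motion and uniform scaling", {
  set.seed(4)
  pts <- matrix(rnorm(300), ncol = 3) %*% diag(c(4, 2, 1))
  e0 <- chain_eccentricity(pts)
  for (s in 1:3) {
    rot <- random_rotation(s)
    moved <- sweep(pts %*% t(rot), 2, c(10, -3, 7), `+`)
    expect_equal(chain_eccentricity(moved), e0, tolerance = 1e-9)
  }
  expect_equal(chain_eccentricity(pts * 123.4), e0, tolerance = 1e-9)
})

test_that("degenerate point clouds are flagged undefined", {
  pts <- matrix(rep(c(1, 2, 3), 10), ncol = 3, byrow = TRUE)
  expect_true(is.na(chain_eccentricity(pts)))
})

test_that("chain extraction separates objects and filters small specks", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(80, 60, 30),
    chains = data.frame(a_um = c(10, 8), b_um = c(5, 4), c_um = c(2, 2)),
    seed = 5
  ))
  ch <- extract_chains(ph$masks$dcx, 20)
  expect_equal(nrow(ch), 2L)

  # scatter single-voxel specks: excluded by the volume gate, kept without it
  m <- ph$masks$dcx$data
  set.seed(6)
  specks <- cbind(sample(2:79, 15), sample(2:59, 15), sample(2:29, 15))
  m[specks] <- TRUE
  noisy <- voxel_mask(m, c(1, 1, 1), "dcx")
  gated <- extract_chains(noisy, min_volume_um3 = 20)
  ungated <- extract_chains(noisy, min_volume_um3 = 1)
  brute <- label_components(noisy, 26, min_size = 20)
  expect_equal(nrow(gated), nrow(brute$sizes))
  expect_gt(nrow(ungated), nrow(gated))
})

test_that("chain density is DCX voxels over niche voxels, ROI-restricted", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(60, 60, 20),
    chains = data.frame(a_um = 9, b_um = 4, c_um = 2), seed = 7
  ))
  dcx <- ph$masks$dcx
  full <- voxel_mask(array(TRUE, dim(dcx$data)), dcx$spacing)
  expect_equal(chain_density(dcx, dcx), 1.0)
  empty <- voxel_mask(array(FALSE, dim(dcx$data)), dcx$spacing)
  expect_equal(chain_density(empty, full), 0.0)
  # truth fraction recovered within 10%
  truth <- ph$truth$chain_volume_fraction
  expect_lt(abs(chain_density(dcx, full) - truth) / truth, 0.10)
  # ROI restriction: a half-volume ROI containing the whole chain doubles it
  roi <- array(FALSE, dim(dcx$data))
  roi[, , 1:20] <- TRUE
  expect_equal(chain_density(dcx, full, voxel_mask(roi, dcx$spacing)),
               chain_density(dcx, full))
  expect_error(chain_density(dcx, empty), "empty niche")
})
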