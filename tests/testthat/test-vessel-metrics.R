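test_that("branch tortuosity of digital paths behaves like arc over chord", {
  # axis-aligned straight path
  path <- cbind(1:20, 5, 5)
  expect_equal(branch_tortuosity(path, c(1, 1, 1)), 1.0)
  # tortuosity is never below 1 and closed loops are flagged undefined
  loop <- rbind(cbind(1:5, 1, 1), cbind(5:1, 2, 1))
  loop <- rbind(loop, loop[1, ])
  expect_true(is.na(branch_tortuosity(loop, c(1, 1, 1))))
})

test_that("phantom tube tortuosity matches analytic values after skeletonization", {
  # straight tube: exactly 1 within 2%
  ph <- straight_tube_phantom(radius_um = 3)
  br <- vessel_branches(ph$masks$laminin)
  expect_lt(abs(median(br$tortuosity) - 1), 0.02)

  # semicircular tube: pi/2 within 5%
  ph <- arc_tube_phantom(radius_um = 3)
  br <- vessel_branches(ph$masks$laminin)
  expect_lt(abs(br$tortuosity[1] - pi / 2) / (pi / 2), 0.05)

  # sine tube: quadrature oracle within 5%
  ph <- sine_tube_phantom(amplitude = 10, wavelength = 50)
  br <- vessel_branches(ph$masks$laminin)
  oracle <- sine_tortuosity_quadrature(10, 50, 99)
  expect_lt(abs(br$tortuosity[1] - oracle) / oracle, 0.05)
})

test_that("tortuosity is invariant under phantom rotation and uniform scaling", {
  base <- sine_tube_phantom(amplitude = 8, wavelength = 40)
  t_base <- vessel_branches(base$masks$laminin)$tortuosity[1]
  # axis swap = 90 degree rotation of the volume
  rot <- aperm(base$masks$laminin$data, c(2, 1, 3))
  t_rot <- vessel_branches(voxel_mask(rot, c(1, 1, 1)))$tortuosity[1]
  expect_equal(t_rot, t_base, tolerance = 0.02)
  # uniform scaling of the spacing leaves the ratio unchanged
  scaled <- voxel_mask(base$masks$laminin$data, c(2.5, 2.5, 2.5))
  t_scaled <- vessel_branches(scaled)$tortuosity[1]
  expect_equal(t_scaled, t_base, tolerance = 1e-9)
})

test_that("skeleton diameters recover phantom tube radii within one voxel", {
  br3 <- vessel_branches(straight_tube_phantom(3)$masks$laminin)
  expect_lte(abs(br3$mean_diameter_um - 6), 1)
  br45 <- vessel_branches(straight_tube_phantom(4.5)$masks$laminin)
  expect_lte(abs(br45$mean_diameter_um - 9), 1)
  # distance-transform radii agree with a brute-force oracle on a crop
  ph <- straight_tube_phantom(4.5, dim = c(60, 24, 24))
  rmap <- distance_transform(ph$masks$laminin, "background")
  crop <- ph$masks$laminin$data
  bf <- brute_force_distance(!crop, c(1, 1, 1))
  expect_equal(rmap, bf, tolerance = 1e-9)
})

test_that("a branch voxel outside the vessel mask is an inconsistency error", {
  ph <- straight_tube_phantom(3, dim = c(40, 20, 20))
  rmap <- distance_transform(ph$masks$laminin, "background")
  outside <- cbind(2, 2, 2) # background corner
  expect_error(branch_diameter(outside, rmap), "outside")
})

test_that("capillary classification honours the 10 um cutoff", {
  ph <- straight_tube_phantom(3)       # ~6 um diameter
  expect_true(all(vessel_branches(ph$masks$laminin)$is_capillary))
  ph_big <- straight_tube_phantom(6, dim = c(80, 40, 40)) # ~12 um
  expect_false(any(vessel_branches(ph_big$masks$laminin)$is_capillary))
})

test_that("vessel density is the vessel-to-niche volume ratio", {
  ph <- straight_tube_phantom(3, dim = c(60, 40, 20))
  vm <- ph$masks$laminin
  full <- voxel_mask(array(TRUE, dim(vm$data)), vm$spacing)
  expect_equal(vessel_density(vm, vm), 1.0)
  empty <- voxel_mask(array(FALSE, dim(vm$data)), vm$spacing)
  expect_equal(vessel_density(empty, full), 0.0)
  # phantom truth fraction recovered within 10% relative
  dens <- vessel_density(vm, full)
  truth <- ph$truth$vessel_volume_fraction
  expect_lt(abs(dens - truth) / truth, 0.10)
  # vessels outside the niche are a containment error
  expect_error(vessel_density(full, vm), "outside")
})

test_that("density is invariant to padding both masks with empty space", {
  ph <- straight_tube_phantom(3, dim = c(40, 20, 20))
  vm <- ph$masks$laminin$data
  niche <- array(TRUE, dim(vm))
  d0 <- vessel_density(voxel_mask(vm, c(1, 1, 1)),
                       voxel_mask(niche, c(1, 1, 1)))
  pad <- function(a, fill) {
    out <- array(fill, dim(a) + c(10L, 0L, 0L))
    out[1:dim(a)[1], , ] <- a
    out
  }
  d1 <- vessel_density(voxel_mask(pad(vm, FALSE), c(1, 1, 1)),
                       voxel_mask(pad(niche, FALSE), c(1, 1, 1)))
  expect_equal(d1, d0)
})

test_that("diameter samples support per-branch and per-voxel weighting", {
  br <- tibble::tibble(
    branch_id = 1:3, mean_diameter_um = c(4, 6, 8),
    local_diameters = list(rep(4, 2), rep(6, 3), rep(8, 5))
  )
  expect_equal(diameter_distribution(br, "per_branch"), c(4, 6, 8))
  expect_equal(diameter_distribution(br, "per_voxel"),
               rep(c(4, 6, 8), c(2, 3, 5)))
  same <- diameter_distribution(br, "per_branch")
  expect_equal(ks_two_sample(same, same)$statistic, 0)
})

test_that("bimodal phantom radii produce diameter modes near the true values", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(100, 60, 30),
    vessels = data.frame(kind = "straight", radius_um = c(3, 4.125),
                         y_um = c(18, 42), z_um = 15),
    seed = 3
  ))
  br <- vessel_branches(ph$masks$laminin)
  d <- sort(br$mean_diameter_um)
  expect_equal(length(d), 2L)
  expect_lt(abs(d[1] - 6), 1)
  expect_lt(abs(d[2] - 8.25), 1)
})
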