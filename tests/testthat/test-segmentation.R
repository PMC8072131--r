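test_that("Otsu segmentation of a clean two-level phantom equals the truth mask", {
  ph <- straight_tube_phantom(radius_um = 3, dim = c(60, 40, 20))
  m <- segment_channel(ph$channels$laminin, method = "otsu")
  expect_identical(m$data, ph$masks$laminin$data)
})

test_that("noisy phantoms segment with high Dice overlap against truth", {
  ph <- generate_niche_phantom(phantom_spec(
    dim = c(60, 40, 20),
    vessels = data.frame(kind = "straight", radius_um = 3, y_um = 20,
                         z_um = 10),
    noise_sd = 38, seed = 6 # 20% of the 190-unit contrast
  ))
  m <- segment_channel(ph$channels$laminin, method = "otsu",
                       smoothing_sigma_um = 0.8)
  truth <- ph$masks$laminin$data
  dice <- 2 * sum(m$data & truth) / (sum(m$data) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("fixed thresholding is strict and handles empty results", {
  g <- voxel_grid(array(50, c(10, 10, 5)), c(1, 1, 1))
  m <- segment_channel(g, method = "fixed", threshold = 100)
  expect_false(any(m$data))
  m2 <- segment_channel(g, method = "fixed", threshold = 50)
  expect_false(any(m2$data)) # strictly above
  expect_error(segment_channel(g, method = "fixed"), "threshold")
  expect_error(segment_channel(g, method = "otsu"), "degenerate")
})

test_that("foreground count is monotone non-increasing in the fixed threshold", {
  set.seed(8)
  g <- voxel_grid(array(round(runif(2000) * 255), c(20, 10, 10)), c(1, 1, 1))
  counts <- vapply(seq(0, 250, by = 25), function(th) {
    sum(segment_channel(g, "fixed", threshold = th)$data)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("the niche mask closes gaps and always contains every channel mask", {
  # two 10-voxel cubes, faces 5 um apart, closing radius 5 -> one component
  m <- array(FALSE, c(40, 40, 40))
  m[10:19, 16:25, 16:25] <- TRUE
  m[25:34, 16:25, 16:25] <- TRUE
  vm <- voxel_mask(m, c(1, 1, 1))
  niche <- compute_niche_mask(list(vm), closing_radius_um = 5)
  expect_equal(nrow(label_components(niche, 26)$sizes), 1L)
  expect_true(all(niche$data[m]))

  # solid slab passes through unchanged
  slab <- array(FALSE, c(20, 20, 10))
  slab[3:18, 3:18, 3:8] <- TRUE
  sm <- voxel_mask(slab, c(1, 1, 1))
  out <- compute_niche_mask(list(sm), closing_radius_um = 2)
  expect_true(all(out$data[slab]))
  expect_gte(sum(out$data), sum(slab))

  expect_error(compute_niche_mask(list(voxel_mask(array(FALSE, c(5, 5, 5)),
                                                  c(1, 1, 1)))),
               "empty niche")
})

test_that("niche volume always bounds the vessel volume from above", {
  ph <- straight_tube_phantom(radius_um = 3, dim = c(50, 30, 20))
  niche <- compute_niche_mask(list(ph$masks$laminin), closing_radius_um = 4)
  expect_gte(sum(niche$data), sum(ph$masks$laminin$data))
  expect_lte(vessel_density(ph$masks$laminin, niche), 1)
})

test_that("connectivity controls whether corner-touching cubes merge", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:5, 2:5, 2:5] <- TRUE
  m[6:9, 6:9, 6:9] <- TRUE # touches the first cube only at one corner
  vm <- voxel_mask(m, c(1, 1, 1))
  expect_equal(nrow(label_components(vm, 26)$sizes), 1L)
  expect_equal(nrow(label_components(vm, 6)$sizes), 2L)
})

test_that("labelling filters small components exactly as a brute-force filter", {
  set.seed(10)
  m <- array(FALSE, c(30, 30, 15))
  for (i in 1:40) { # scatter specks of 1-3 voxels
    p <- c(sample(2:29, 1), sample(2:29, 1), sample(2:14, 1))
    m[p[1], p[2], p[3]] <- TRUE
    if (runif(1) < 0.5) m[p[1] + 1, p[2], p[3]] <- TRUE
  }
  vm <- voxel_mask(m, c(1, 1, 1))
  all_sizes <- label_components(vm, 26, min_size = 1)$sizes$n_voxels
  for (min_size in c(1, 2, 3, 50)) {
    surv <- label_components(vm, 26, min_size = min_size)$sizes
    expect_equal(nrow(surv), sum(all_sizes >= min_size))
    if (nrow(surv) > 1) expect_true(all(diff(surv$n_voxels) <= 0))
  }
})

test_that("an empty mask labels to zero objects", {
  lab <- label_components(voxel_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1)))
  expect_equal(nrow(lab$sizes), 0L)
  expect_true(all(lab$labels == 0L))
})
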