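cell_phantom <- function(seed = 3) {
  generate_niche_phantom(phantom_spec(
    dim = c(100, 80, 30),
    vessels = data.frame(kind = "straight", radius_um = 3, y_um = 40,
                         z_um = 8),
    cells = data.frame(n = c(10, 10), radius_um = 3, depth_um = c(3, 8),
                       vessel_distance_um = c(8, 15),
                       gfap = c(TRUE, FALSE), ki67 = c(FALSE, TRUE)),
    seed = seed
  ))
}

test_that("nucleus detection recovers count and centroids from the phantom", {
  ph <- cell_phantom()
  cells <- detect_nuclei(ph$masks$dapi)
  expect_equal(nrow(cells), 20L)
  tr <- ph$truth$cells
  half_diag <- sqrt(3) / 2
  for (r in seq_len(nrow(cells))) {
    d <- sqrt(min((tr$x_um - cells$x_um[r])^2 + (tr$y_um - cells$y_um[r])^2 +
                    (tr$z_um - cells$z_um[r])^2))
    expect_lt(d, half_diag)
  }
})

test_that("nuclei outside the volume window are excluded", {
  m <- array(FALSE, c(40, 40, 20))
  m[5:8, 5:8, 5:8] <- TRUE            # 64 um3, in bounds
  m[15:34, 15:34, 5:16] <- TRUE       # 4800 um3 blob, oversized
  cells <- detect_nuclei(voxel_mask(m, c(1, 1, 1)), min_volume_um3 = 10,
                         max_volume_um3 = 1000)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$volume_um3, 64)
})

test_that("GFAP positivity is an inclusive overlap-fraction threshold", {
  # nucleus fully inside GFAP
  nuc <- array(FALSE, c(20, 20, 10)); nuc[5:8, 5:8, 4:6] <- TRUE
  gf_all <- voxel_mask(array(TRUE, dim(nuc)), c(1, 1, 1))
  cells <- detect_nuclei(voxel_mask(nuc, c(1, 1, 1)))
  out <- classify_gfap(cells, gf_all, 0.3)
  expect_equal(out$gfap_overlap, 1)
  expect_true(out$gfap_pos)

  # zero overlap
  gf_none <- voxel_mask(array(FALSE, dim(nuc)), c(1, 1, 1))
  expect_false(classify_gfap(cells, gf_none, 0.3)$gfap_pos)

  # constructed 30% overlap is positive at threshold 0.3 (boundary inclusive)
  nuc2 <- array(FALSE, c(20, 20, 10)); nuc2[1:10, 1, 1] <- TRUE
  gf <- array(FALSE, c(20, 20, 10)); gf[1:3, 1, 1] <- TRUE
  cells2 <- detect_nuclei(voxel_mask(nuc2, c(1, 1, 1)), min_volume_um3 = 1)
  out2 <- classify_gfap(cells2, voxel_mask(gf, c(1, 1, 1)), 0.3)
  brute <- sum(nuc2 & gf) / sum(nuc2)
  expect_equal(out2$gfap_overlap, brute)
  expect_equal(brute, 0.3)
  expect_true(out2$gfap_pos)
  expect_false(classify_gfap(cells2, voxel_mask(gf, c(1, 1, 1)),
                             0.31)$gfap_pos)
})

test_that("raising the overlap threshold never adds positives", {
  ph <- cell_phantom()
  cells <- detect_nuclei(ph$masks$dapi)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    sum(classify_gfap(cells, ph$masks$gfap, th)$gfap_pos)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("the apical filter keeps cells at or under the depth threshold", {
  cells <- tibble::tibble(cell_id = 1:3, apical_depth_um = c(4, 6, 0))
  kept <- filter_apical(cells, 5)
  expect_equal(kept$cell_id, c(1L, 3L))
  expect_error(filter_apical(cells, -1), ">= 0")

  # phantom: 10 cells at 3 um, 10 at 8 um -> exactly 10 apical
  ph <- cell_phantom()
  cells <- detect_nuclei(ph$masks$dapi)
  expect_equal(nrow(filter_apical(cells, 5)), 10L)
  expect_true(all(filter_apical(cells, 5)$apical_depth_um <= 5))
})

test_that("marker counts respect flags, ROI masks and monotonicity", {
  ph <- cell_phantom()
  cells <- detect_nuclei(ph$masks$dapi)
  cells <- classify_gfap(cells, ph$masks$gfap, 0.3)
  cells <- classify_ki67(cells, ph$masks$ki67, 0.3)
  expect_equal(count_marker(cells, "gfap"), 10L)
  expect_equal(count_marker(cells, "ki67"), 10L)

  # anterior-half ROI: counts never exceed the whole-niche counts
  roi <- array(FALSE, dim(ph$masks$dapi$data))
  roi[1:50, , ] <- TRUE
  roi_mask <- voxel_mask(roi, c(1, 1, 1))
  n_roi <- count_marker(cells, "ki67", roi_mask)
  expect_lte(n_roi, count_marker(cells, "ki67"))
  n_inside <- sum(cells$ki67_pos & cells$x_um <= 49)
  expect_equal(n_roi, n_inside)

  none <- dplyr::mutate(cells, ki67_pos = FALSE)
  expect_equal(count_marker(none, "ki67"), 0L)
  expect_error(count_marker(dplyr::select(cells, -"ki67_pos"), "ki67"),
               "classify")
})
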