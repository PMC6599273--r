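test_that("window transform maps HU to display grey linearly with clipping", {
  lw <- lung_window()
  expect_equal(apply_window(-400, lw), 0.5)   # level -> mid-grey
  expect_equal(apply_window(350, lw), 1.0)    # ceiling
  expect_equal(apply_window(-1150, lw), 0.0)  # floor
  mw <- mediastinal_window()
  expect_equal(apply_window(-160, mw), 0.0)   # mediastinal floor = 40 - 200
  expect_equal(apply_window(240, mw), 1.0)
  expect_error(window_setting(-10, 0), "width")
})

test_that("window transform is order preserving and idempotent after rescale", {
  set.seed(1)
  hu <- sort(runif(200, -1200, 400))
  d <- apply_window(hu, lung_window())
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
  # rescaling a clipped display back to HU and re-windowing is a fixed point
  lw <- lung_window()
  hu2 <- lw$floor + d * lw$width
  expect_equal(apply_window(hu2, lw), d)
})

test_that("threshold segmentation separates core and rim by window", {
  v <- make_sphere_volume(r_core = 4, r_out = 7, core_hu = 40, rim_hu = -500)
  seed <- round(dim(v$data) / 2) - 1L  # 0-based centre
  lw_mask <- segment_window(v, lung_window(), seed)
  mw_mask <- segment_window(v, mediastinal_window(), seed)
  # lung window sees core + rim, mediastinal window only the core
  expect_gt(sum(lw_mask), sum(mw_mask))
  expect_true(all(mw_mask[lw_mask == FALSE] == FALSE))
  expect_equal(sum(mw_mask), sum(v$data >= -160 & v$data > -700))
  # volumes close to the analytic sphere volumes
  expect_equal(mask_volume(lw_mask, v$spacing), 4 / 3 * pi * 7^3, tolerance = 0.1)
  expect_equal(mask_volume(mw_mask, v$spacing), 4 / 3 * pi * 4^3, tolerance = 0.15)
})

test_that("pure ground-glass nodule yields empty mediastinal mask, DR = LW", {
  v <- make_sphere_volume(r_core = 0, r_out = 6, rim_hu = -500)
  seed <- round(dim(v$data) / 2) - 1L
  expect_error(segment_window(v, mediastinal_window(), seed), "seed not in nodule")
  ms <- nodule_masks(v, seed)
  expect_equal(sum(ms$mw_mask), 0)
  expect_true(isTRUE(attr(ms$mw_mask, "empty")))
  expect_identical(which(ms$dr_mask), which(ms$lw_mask))
})

test_that("segmentation keeps only the seeded component", {
  v <- make_sphere_volume(dim = c(32, 32, 32), centre = c(9, 9, 9), r_core = 4)
  # second disjoint nodule
  idx <- which(array(TRUE, dim(v$data)), arr.ind = TRUE)
  d2 <- sqrt(rowSums(sweep(idx, 2, c(24, 24, 24))^2))
  v$data[d2 <= 4] <- 40
  m <- segment_window(v, mediastinal_window(), c(8, 8, 8))
  # oracle: the thresholded grid has two components; the mask is the seeded
  # one only, so it misses the second sphere entirely
  expect_gt(sum(m), 0)
  expect_false(any(m[d2 <= 4]))
  above <- v$data >= -160
  expect_lt(sum(m), sum(above))
  # both components together cover the thresholded voxels (after closing
  # the seeded one is no smaller than its raw component)
  m2 <- segment_window(v, mediastinal_window(), c(23, 23, 23))
  expect_false(any(m2 & m))
  expect_gte(sum(m) + sum(m2), sum(above))
})

test_that("mask monotonicity: higher threshold never grows the mask", {
  v <- make_sphere_volume(r_core = 5, r_out = 8, noise_sd = 30, seed = 3)
  seed <- round(dim(v$data) / 2) - 1L
  thresholds <- c(-750, -500, -200, 0)
  prev <- NULL
  for (t in thresholds) {
    m <- v$data >= t  # voxelwise pre-closing monotonicity
    if (!is.null(prev)) expect_true(all(!m | prev))
    prev <- m
  }
})

test_that("difference region obeys the mask-algebra identity", {
  lw <- array(FALSE, c(6, 6, 6)); lw[2:5, 2:5, 2:5] <- TRUE
  mw_empty <- array(FALSE, c(6, 6, 6))
  expect_identical(difference_region(lw, mw_empty), lw & TRUE)
  expect_equal(sum(difference_region(lw, lw)), 0)
  expect_error(difference_region(lw, array(FALSE, c(5, 6, 6))), "align")

  # |DR| = |LW| - |LW & MW| on 100 random mask pairs, against a brute-force
  # voxel-loop oracle
  set.seed(99)
  for (i in 1:100) {
    lw <- array(runif(4^3) < 0.4, c(4, 4, 4))
    mw <- array(runif(4^3) < 0.4, c(4, 4, 4))
    dr <- difference_region(lw, mw)
    expect_equal(sum(dr), oracle_diff_count(lw, mw))
    expect_equal(sum(dr) + sum(lw & mw), sum(lw))
  }
})

test_that("nested default thresholds give mw inside lw and exact volume split", {
  v <- make_sphere_volume(r_core = 4, r_out = 7, noise_sd = 20, seed = 5)
  seed <- round(dim(v$data) / 2) - 1L
  ms <- nodule_masks(v, seed)
  expect_true(all(!ms$mw_mask | ms$lw_mask))  # mw subset of lw
  expect_equal(sum(ms$dr_mask), sum(ms$lw_mask) - sum(ms$mw_mask))
})

test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- TRUE
  expect_equal(mask_volume(m, c(1, 1, 1)), 100)
  expect_equal(mask_volume(m, c(0.7, 0.7, 2.5)), 100 * 0.7 * 0.7 * 2.5)
  expect_equal(mask_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
  expect_error(mask_volume(m, c(-1, 1, 1)), "positive")
})

test_that("volumes and masks round-trip through NIfTI with spacing", {
  skip_if_not_installed("RNifti")
  v <- make_sphere_volume(dim = c(12, 12, 12), r_core = 3,
                          spacing = c(0.7, 0.7, 2.5))
  p <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, p)
  v2 <- read_volume_nifti(p)
  expect_equal(v2$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  m <- v$data >= -160
  pm <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, pm, spacing = v$spacing)
  m2 <- read_mask_nifti(pm)
  expect_equal(array(m2, dim(m)), m, ignore_attr = TRUE)
})
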