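test_that("fraction 1.0 segments exactly the peak voxel", {
  sp <- small_spec(noise_sd = 0, psf_fwhm = 0)
  p <- generate_phantom_pair(sp)
  roi <- elliptical_roi(sp$tumour_center, 1.5 * sp$tumour_radii)
  m <- threshold_segment(p$pre_pet, roi, threshold_spec(fraction = 1))
  expect_equal(sum(m$data), 1)
  peak <- suv_max_in_roi(p$pre_pet, roi)
  expect_true(m$data[peak$linear_index])
})

test_that("relative threshold of a Gaussian blob matches the analytic iso-volume", {
  # isotropic Gaussian profile, no truncation inside the ROI: the f-threshold
  # region is the ball r <= sigma * sqrt(-2 log f)
  d <- c(48, 48, 48); spacing <- c(2, 2, 2); sigma <- 12
  cc <- (d - 1) / 2 * spacing
  vol <- image_volume(array(0, d), spacing)
  w <- expand.grid(x = (seq_len(d[1]) - 1) * 2, y = (seq_len(d[2]) - 1) * 2,
                   z = (seq_len(d[3]) - 1) * 2)
  r2 <- (w$x - cc[1])^2 + (w$y - cc[2])^2 + (w$z - cc[3])^2
  vol$data <- array(10 * exp(-r2 / (2 * sigma^2)), d)
  roi <- elliptical_roi(cc, c(46, 46, 46))
  m <- threshold_segment(vol, roi, threshold_spec(fraction = 0.5))
  r_iso <- sigma * sqrt(-2 * log(0.5))
  v_analytic <- 4 / 3 * pi * r_iso^3 / prod(spacing)
  # one-voxel-shell tolerance around the analytic sphere
  shell <- 4 * pi * r_iso^2 * max(spacing) / prod(spacing)
  expect_lt(abs(sum(m$data) - v_analytic), shell)
})

test_that("only the component containing the SUVmax voxel is kept", {
  d <- c(20, 20, 20)
  arr <- array(0, d)
  arr[4:6, 4:6, 4:6] <- 5      # hot blob (contains the max)
  arr[5, 5, 5] <- 8
  arr[14:16, 14:16, 14:16] <- 5 # disjoint warm blob
  vol <- image_volume(arr, c(1, 1, 1))
  roi <- elliptical_roi(c(9.5, 9.5, 9.5), c(50, 50, 50))
  kept <- threshold_segment(vol, roi, threshold_spec(fraction = 0.5))
  expect_equal(sum(kept$data), 27)
  expect_true(all(which(kept$data) ==
                    which(arr >= 4 &
                          slice.index(arr, 1) <= 6)))
  both <- threshold_segment(vol, roi,
                            threshold_spec(fraction = 0.5,
                                           keep_component_with_max = FALSE))
  expect_equal(sum(both$data), 54)
})

test_that("diagonal touching counts as connected (26-connectivity)", {
  arr <- array(0, c(6, 6, 6))
  arr[2, 2, 2] <- 8
  arr[3, 3, 3] <- 6  # shares only a corner with the max voxel
  arr[5, 5, 5] <- 6  # genuinely disjoint
  vol <- image_volume(arr, c(1, 1, 1))
  roi <- elliptical_roi(c(2.5, 2.5, 2.5), c(20, 20, 20))
  m <- threshold_segment(vol, roi, threshold_spec(fraction = 0.5))
  expect_true(m$data[2, 2, 2] && m$data[3, 3, 3])
  expect_false(m$data[5, 5, 5])
})

test_that("masks nest across fractions and are scale invariant", {
  for (seed in 1:3) {
    sp <- small_spec(seed = seed)
    p <- generate_phantom_pair(sp)
    roi <- elliptical_roi(sp$tumour_center, 1.5 * sp$tumour_radii)
    fr <- c(0.4, 0.5, 0.6, 0.8)
    masks <- lapply(fr, function(f)
      threshold_segment(p$pre_pet, roi, threshold_spec(fraction = f)))
    for (i in seq_len(length(fr) - 1))
      expect_true(all(masks[[i + 1]]$data <= masks[[i]]$data),
                  label = sprintf("nesting %.1f in %.1f (seed %d)",
                                  fr[i + 1], fr[i], seed))
    scaled <- p$pre_pet
    scaled$data <- 3.7 * scaled$data
    m_scaled <- threshold_segment(scaled, roi, threshold_spec(fraction = 0.4))
    expect_identical(m_scaled$data, masks[[1]]$data)
  }
})

test_that("absolute-SUV mode thresholds at the given value", {
  arr <- array(1, c(10, 10, 10)); arr[4:6, 4:6, 4:6] <- 3
  vol <- image_volume(arr, c(1, 1, 1))
  roi <- elliptical_roi(c(4.5, 4.5, 4.5), c(30, 30, 30))
  m <- threshold_segment(vol, roi, threshold_spec(absolute_suv = 2.5))
  expect_equal(sum(m$data), 27)
  expect_error(threshold_spec(fraction = 0.4, absolute_suv = 2.5), "exactly one")
})

test_that("non-avid images cannot be segmented in relative mode", {
  vol <- uvol(0, c(8, 8, 8))
  roi <- elliptical_roi(c(3.5, 3.5, 3.5), c(10, 10, 10))
  expect_error(threshold_segment(vol, roi, threshold_spec(fraction = 0.4)),
               "non-avid")
})

test_that("mask volume is voxel count times voxel volume", {
  m1 <- binary_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(mask_volume_cc(m1), 1.0)
  m2 <- binary_mask(array(TRUE, c(20, 20, 20)), c(2.5, 2.5, 2.5))
  expect_equal(mask_volume_cc(m2), 125.0)
  m0 <- binary_mask(array(FALSE, c(5, 5, 5)), c(2, 2, 2))
  expect_equal(mask_volume_cc(m0), 0.0)
})
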