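test_that("full containment puts the residual entirely inside the 40% region", {
  sp <- small_spec(noise_sd = 0, psf_fwhm = 0, shrinkage = 1, caudal_shift = 0,
                   containment_fraction = 1)
  p <- generate_phantom_pair(sp)
  expect_equal(overlap_fraction(p$pre40_true, p$residual_true), 100)
  expect_equal(p$achieved_containment, 1)
  # post hot region (above background) is inside the baseline 40% region
  hot <- binary_mask(p$post_pet$data > sp$background_suv + 1e-9,
                     sp$spacing, p$post_pet$origin)
  expect_equal(overlap_fraction(p$pre40_true, hot), 100)
})

test_that("requested containment is realised by voxel count", {
  for (rho in c(0.25, 0.5, 0.75)) {
    p <- generate_phantom_pair(small_spec(noise_sd = 0,
                                          containment_fraction = rho))
    counted <- sum(p$residual_true$data & p$pre40_true$data) /
      sum(p$residual_true$data)
    expect_equal(p$achieved_containment, counted)
    # within a one-voxel shell of the residual surface
    r_mean <- mean(p$spec$residual_radii)
    shell_frac <- (4 * pi * r_mean^2 * max(p$spec$spacing)) /
      (4 / 3 * pi * r_mean^3)
    expect_lt(abs(counted - rho), shell_frac)
    expect_lt(abs(counted - rho), 0.05)
  }
})

test_that("phantom peaks hit the requested SUVmax when the PSF is off", {
  sp <- small_spec(baseline_peak_suv = 10.6, post_peak_suv = 5.7,
                   psf_fwhm = 0, noise_sd = 0)
  p <- generate_phantom_pair(sp)
  roi_pre <- elliptical_roi(sp$tumour_center, 1.5 * sp$tumour_radii)
  roi_post <- elliptical_roi(sp$tumour_center + c(0, 0, sp$caudal_shift),
                             1.5 * sp$tumour_radii)
  expect_equal(suv_max_in_roi(p$pre_pet, roi_pre)$suv_max, 10.6)
  expect_equal(suv_max_in_roi(p$post_pet, roi_post)$suv_max, 5.7)
})

test_that("unreachable containment fails naming the limiting axis", {
  expect_error(generate_phantom_pair(
    small_spec(residual_radii = c(17, 15, 13), containment_fraction = 1,
               noise_sd = 0)),
    "limiting axis")
  expect_error(phantom_spec(residual_radii = c(30, 10, 10)), "componentwise")
  expect_error(phantom_spec(post_peak_suv = 9, baseline_peak_suv = 8),
               "allow_post_increase")
  expect_silent(phantom_spec(post_peak_suv = 9, baseline_peak_suv = 8,
                             allow_post_increase = TRUE))
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_phantom_pair(small_spec(seed = 11))
  b <- generate_phantom_pair(small_spec(seed = 11))
  expect_identical(a$pre_pet$data, b$pre_pet$data)
  expect_identical(a$post_pet$data, b$post_pet$data)
  c <- generate_phantom_pair(small_spec(seed = 12))
  expect_false(identical(a$post_pet$data, c$post_pet$data))
})

test_that("PSF blur: identity at zero, spike response, semigroup", {
  set.seed(5)
  vol <- image_volume(array(runif(16^3), c(16, 16, 16)), c(1, 1, 1))
  expect_identical(apply_psf_blur(vol, 0)$data, vol$data)

  # delta spike: response equals the separable normalized kernel
  d <- c(17, 17, 17)
  spike <- image_volume(array(0, d), c(2, 2, 2))
  spike$data[9, 9, 9] <- 1
  fwhm <- 4 # = 2 * spacing
  out <- apply_psf_blur(spike, fwhm)
  expect_lt(max(out$data), 1)
  expect_equal(sum(out$data), 1, tolerance = 1e-6)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / 2
  r <- ceiling(4 * sigma_vox)
  k1 <- exp(-((-r:r)^2) / (2 * sigma_vox^2)); k1 <- k1 / sum(k1)
  expect_equal(out$data[9, 9, 9], k1[r + 1]^3, tolerance = 1e-12)
  expect_equal(out$data[9 + 1, 9, 9], k1[r + 2] * k1[r + 1]^2,
               tolerance = 1e-12)

  # two blurs compose like one blur of quadratically-added width
  two <- apply_psf_blur(apply_psf_blur(vol, 3), 4)
  one <- apply_psf_blur(vol, 5)
  expect_lt(max(abs(two$data - one$data)), 1e-3 * max(vol$data))
})

test_that("measured post SUVmax is non-increasing in PSF width", {
  suvmax <- vapply(c(0, 3, 6, 9), function(fw) {
    sp <- small_spec(noise_sd = 0, psf_fwhm = fw)
    p <- generate_phantom_pair(sp)
    roi <- elliptical_roi(sp$tumour_center + c(0, 0, sp$caudal_shift),
                          1.5 * sp$tumour_radii)
    suv_max_in_roi(p$post_pet, roi)$suv_max
  }, numeric(1))
  expect_true(all(diff(suvmax) < 0))
  expect_equal(suvmax[1], 3.6)
})

test_that("ground-truth field round-trips masks through its numerical inverse", {
  # full-size phantom: the residual must be well-resolved (hundreds of
  # voxels) for the double resample + re-binarization to be near-lossless
  p <- generate_phantom_pair(phantom_spec(noise_sd = 0, shrinkage = 0.85))
  fi <- invert_field(p$field_true)
  rt <- warp_mask(warp_mask(p$residual_true, p$field_true), fi)
  expect_gte(dice_coefficient(rt, p$residual_true), 99)
})

test_that("phantom pairs survive a NIfTI round trip", {
  dir <- withr::local_tempdir()
  p <- generate_phantom_pair(small_spec(seed = 2))
  write_phantom_pair(p, dir)
  back <- read_volume(file.path(dir, "pre_pet.nii.gz"))
  expect_equal(back$data, p$pre_pet$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, p$pre_pet$spacing)
  mback <- read_mask(file.path(dir, "gtv_true.nii.gz"))
  expect_identical(mback$data, p$gtv_true$data)
  side <- jsonlite::read_json(file.path(dir, "phantom.json"))
  expect_equal(side$seed, 2)
  expect_equal(side$achieved_containment, p$achieved_containment)
})
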