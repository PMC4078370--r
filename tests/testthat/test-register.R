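make_ball_mask <- function(d = c(32, 32, 32), spacing = c(2, 2, 2),
                           radius = 14) {
  g <- image_volume(array(0, d), spacing)
  cc <- (d - 1) / 2 * spacing
  roi <- elliptical_roi(cc, rep(radius, 3))
  binary_mask(petbtv:::roi_mask_array(g, roi), spacing)
}

test_that("identity field leaves masks and images unchanged", {
  m <- make_ball_mask()
  f <- identity_field(m)
  expect_identical(warp_mask(m, f)$data, m$data)
  set.seed(3)
  img <- image_volume(array(runif(prod(dim(m$data))), dim(m$data)), m$spacing)
  expect_equal(warp_image(img, f)$data, img$data)
})

test_that("integer-voxel translation shifts masks exactly, conserving volume", {
  m <- make_ball_mask()
  f <- affine_field(m, translation = c(4, -2, 2)) # 2, -1, 1 voxels
  w <- warp_mask(m, f)
  expect_equal(sum(w$data), sum(m$data))
  # fixed x samples moving at x + t: content appears shifted by -t voxels
  d <- dim(m$data)
  expect_identical(w$data[1:(d[1] - 2), 2:d[2], 1:(d[3] - 1)],
                   m$data[3:d[1], 1:(d[2] - 1), 2:d[3]])
})

test_that("uniform scaling obeys the 1/s^3 volume law within 5%", {
  m <- make_ball_mask()
  expect_gt(sum(m$data), 500)
  cc <- (dim(m$data) - 1) / 2 * m$spacing
  for (s in c(0.8, 0.9)) {
    f <- affine_field(m, scale = s, center = cc)
    ratio <- sum(warp_mask(m, f)$data) / sum(m$data)
    expect_equal(ratio, 1 / s^3, tolerance = 0.05)
  }
})

test_that("warping resamples onto the field's (fixed) grid", {
  # moving mask and fixed grid may differ: propagation lands on the fixed grid
  m <- make_ball_mask(d = c(32, 32, 32), spacing = c(2, 2, 2))
  fixed <- image_volume(array(0, c(16, 16, 16)), c(4, 4, 4))
  w <- warp_mask(m, identity_field(fixed))
  expect_identical(dim(w$data), dim(fixed$data))
  expect_equal(w$spacing, fixed$spacing)
  # volume is preserved up to resampling error on the coarser grid
  expect_equal(mask_volume_cc(w), mask_volume_cc(m), tolerance = 0.1)
  expect_error(binary_mask(array(NA, c(2, 2, 2)), c(1, 1, 1)), "NA")
})

test_that("field validation reports Jacobians and flags folds", {
  m <- make_ball_mask(d = c(16, 16, 16))
  v_id <- validate_field(identity_field(m))
  expect_true(v_id$ok)
  expect_equal(v_id$min_jacobian, 1)
  expect_equal(v_id$max_jacobian, 1)
  expect_equal(v_id$max_displacement_mm, 0)

  v_tr <- validate_field(affine_field(m, translation = c(5, 0, -3)))
  expect_true(v_tr$ok)
  expect_equal(v_tr$min_jacobian, 1)
  expect_equal(v_tr$max_displacement_mm, sqrt(25 + 9))

  v_sc <- validate_field(affine_field(m, scale = 0.8))
  expect_equal(v_sc$min_jacobian, 0.8^3, tolerance = 1e-9)

  # constructed fold: displacement reverses orientation along x in one slab.
  # finite-difference oracle: dx jumps by -2*spacing across one voxel, so
  # d(x + dx)/dx = 1 - 2 = -1 < 0 there
  g <- image_volume(array(0, c(12, 12, 12)), c(2, 2, 2))
  dx <- array(0, c(12, 12, 12)); dx[7:12, , ] <- -8
  fold <- deformation_field(dx, array(0, dim(dx)), array(0, dim(dx)),
                            g$spacing, g$origin)
  v_f <- validate_field(fold)
  expect_false(v_f$ok)
  expect_lt(v_f$min_jacobian, 0)
  expect_gt(v_f$folding_fraction, 0)
})

test_that("smooth fields invert to high mask agreement", {
  m <- make_ball_mask()
  cc <- (dim(m$data) - 1) / 2 * m$spacing
  f <- affine_field(m, scale = 0.85, center = cc, translation = c(3, -2, 5))
  fi <- invert_field(f)
  # analytic inverse of x -> c + s(x-c) + t has displacement (x - t - c)(1/s - 1) - t/s... check by composition instead
  rt <- warp_mask(warp_mask(m, f), fi)
  expect_gte(dice_coefficient(rt, m), 99)
  v <- validate_field(fi)
  expect_true(v$ok)
})

test_that("rigid alignment recovers translations", {
  sp <- small_spec(noise_sd = 0, psf_fwhm = 6, seed = 4)
  p <- generate_phantom_pair(sp)
  fixed <- p$pre_pet

  same <- rigid_align(fixed, fixed, search_mm = 6)
  expect_equal(same$translation_mm, c(0, 0, 0))
  expect_equal(same$ncc, 1)

  # moving = fixed content shifted by a known integer-voxel world offset
  off <- c(5, -2.5, 2.5)
  moving <- image_volume(fixed$data, fixed$spacing, fixed$origin - off)
  got <- rigid_align(moving, fixed, search_mm = 8)
  expect_equal(got$translation_mm, -off)
  expect_equal(got$ncc, 1, tolerance = 1e-12)

  # with noise at 5% of the dynamic range: within one voxel per axis
  set.seed(99)
  noisy <- moving
  noisy$data <- noisy$data + array(rnorm(length(noisy$data),
                                         sd = 0.05 * diff(range(fixed$data))),
                                   dim(noisy$data))
  got_n <- rigid_align(noisy, fixed, search_mm = 8)
  expect_true(all(abs(got_n$translation_mm - (-off)) <= fixed$spacing))

  expect_error(rigid_align(uvol(1), uvol(2)), "degenerate")
})
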