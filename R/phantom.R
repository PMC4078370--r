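#' Specification of a paired pre/post-treatment PET phantom
#'
#' Describes a synthetic pancreatic-tumour scan pair with known ground truth.
#' The baseline tumour is an ellipsoidal Gaussian uptake blob inside a GTV
#' ellipsoid; the post-treatment scan contains a smaller residual hot region
#' whose containment inside the baseline 40%-of-peak region is a controlled
#' parameter, and whose anatomy is additionally shrunk about the tumour
#' center and shifted caudally (third axis, increasing index = inferior)
#' before scanner blur and noise are applied.
#'
#' Defaults emulate the cohort being modelled: a ~41 cm^3 GTV, baseline peak
#' SUV 8.0 and post-treatment peak 3.6 (the cohort medians), a ~7 cm^3
#' residual (the mean 60%-threshold post-treatment volume), 6 mm PSF
#' (clinical PET resolution), 2.5 mm grid.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Numeric length-3, mm.
#' @param tumour_center World mm; default = grid center.
#' @param tumour_radii Ellipsoid semi-axes of the GTV, mm.
#' @param background_suv Background SUV level.
#' @param baseline_peak_suv Target SUVmax of the baseline scan.
#' @param post_peak_suv Target SUVmax of the post-treatment scan.
#' @param residual_radii Semi-axes of the residual hot ellipsoid, mm
#'   (componentwise <= `tumour_radii`).
#' @param containment_fraction Fraction in `[0, 1]` of the residual region's
#'   volume placed inside the baseline 40%-of-peak region (measured on the
#'   planning grid, before deformation).
#' @param shrinkage Linear shrink factor in (0, 1] applied about
#'   `tumour_center` between scans.
#' @param caudal_shift Tumour translation along the third axis, mm.
#' @param psf_fwhm Scanner point-spread FWHM, mm (isotropic Gaussian).
#' @param noise_sd Additive Gaussian noise sd, SUV units.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @param allow_post_increase Permit `post_peak_suv > baseline_peak_suv`
#'   (a progressing tumour); off by default.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(2.5, 2.5, 2.5),
                         tumour_center = NULL,
                         tumour_radii = c(25, 22, 18),
                         background_suv = 1,
                         baseline_peak_suv = 8,
                         post_peak_suv = 3.6,
                         residual_radii = c(14, 12, 10),
                         containment_fraction = 0.85,
                         shrinkage = 0.85,
                         caudal_shift = 5,
                         psf_fwhm = 6,
                         noise_sd = 0.2,
                         seed = 1L,
                         allow_post_increase = FALSE) {
  grid_shape <- as.integer(grid_shape); spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(tumour_center)) # snap to a voxel center so the peak is unique
    tumour_center <- floor((grid_shape - 1) / 2) * spacing
  if (any(residual_radii > tumour_radii))
    stop("residual_radii must be <= tumour_radii componentwise")
  if (post_peak_suv > baseline_peak_suv && !allow_post_increase)
    stop("post_peak_suv exceeds baseline_peak_suv; ",
         "set allow_post_increase = TRUE to model a progressing tumour")
  if (containment_fraction < 0 || containment_fraction > 1)
    stop("containment_fraction must be in [0, 1]")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  if (background_suv >= 0.4 * baseline_peak_suv)
    stop("background_suv must be below 40% of baseline_peak_suv, ",
         "otherwise the baseline 40% region is unbounded")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 tumour_center = as.numeric(tumour_center),
                 tumour_radii = as.numeric(tumour_radii),
                 background_suv = background_suv,
                 baseline_peak_suv = baseline_peak_suv,
                 post_peak_suv = post_peak_suv,
                 residual_radii = as.numeric(residual_radii),
                 containment_fraction = containment_fraction,
                 shrinkage = shrinkage, caudal_shift = caudal_shift,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gaussian point-spread blur
#'
#' Separable Gaussian convolution with per-axis sigma `fwhm / (2 sqrt(2 ln 2))
#' / spacing` voxels, normalized kernel, reflective boundary handling. Models
#' the finite scanner resolution responsible for the recovery-coefficient
#' (partial-volume) underestimation of small hot objects. `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param img An [image_volume()].
#' @param fwhm_mm Full width at half maximum, mm (>= 0).
#' @return A blurred `image_volume` on the same grid.
#' @export
apply_psf_blur <- function(img, fwhm_mm) {
  stopifnot(inherits(img, "image_volume"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(img)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  arr <- img$data
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / img$spacing[axis]
    arr <- convolve_axis_gauss(arr, axis, sigma_vox)
  }
  out <- img
  out$data <- arr
  out
}

# 1D Gaussian convolution along `axis`, reflective padding, via shifted
# matrix accumulation (vectorized over the other two axes)
convolve_axis_gauss <- function(arr, axis, sigma_vox) {
  d <- dim(arr)
  n <- d[axis]
  r <- min(ceiling(4 * sigma_vox), n - 1L)
  if (r < 1L && sigma_vox < 1e-3) return(arr)
  r <- max(r, 1L)
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  pad_idx <- c(r:1, 1:n, n:(n - r + 1L))
  p <- m[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * p[(j - 1L) + seq_len(n), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

# ellipsoid indicator over grid world coords
ellipsoid_mask_arr <- function(w, center, radii) {
  ((w$x - center[1]) / radii[1])^2 + ((w$y - center[2]) / radii[2])^2 +
    ((w$z - center[3]) / radii[3])^2 <= 1
}

# Gaussian uptake profile truncated at an ellipsoid boundary: background
# outside, background + exp(-q/2) inside, with sigma = radii / 2 (unscaled
# amplitude; scale to a target peak afterwards)
uptake_profile <- function(xs, ys, zs, center, radii) {
  s <- radii / 2
  q <- ((xs - center[1]) / s[1])^2 + ((ys - center[2]) / s[2])^2 +
    ((zs - center[3]) / s[3])^2
  inside <- ((xs - center[1]) / radii[1])^2 + ((ys - center[2]) / radii[2])^2 +
    ((zs - center[3]) / radii[3])^2 <= 1
  exp(-q / 2) * inside
}

#' Generate a paired pre/post-treatment PET phantom
#'
#' Builds the baseline scan, solves for the residual-region position that
#' realises the requested containment inside the baseline 40%-of-peak region
#' (bisection on the voxel-counted containment along the first axis), applies
#' the ground-truth deformation (shrinkage about the tumour center composed
#' with a caudal translation) to the post-treatment anatomy, then scanner
#' blur and seeded noise. The returned deformation field is exact and maps
#' planning-grid points into the post-scan space (pull-back), so warping the
#' post-treatment masks by `field_true` brings them onto the planning grid.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair`: `pre_pet`, `post_pet`
#'   (SUV `image_volume`s), `pre_ct`, `post_ct`, `gtv_true`, `residual_true`,
#'   `pre40_true` ([binary_mask()]s on the planning grid), `field_true`
#'   (a [deformation_field()]), `achieved_containment` (voxel-counted), and
#'   `spec`.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- image_volume(array(0, spec$grid_shape), spec$spacing)
  w <- grid_world_coords(geom)
  cc <- spec$tumour_center
  bg <- spec$background_suv

  # baseline scan (noise-free, pre-blur), scaled so the max voxel hits the peak
  g_pre <- uptake_profile(w$x, w$y, w$z, cc, spec$tumour_radii)
  if (max(g_pre) == 0) stop("tumour ellipsoid contains no voxel centers")
  amp_pre <- (spec$baseline_peak_suv - bg) / max(g_pre)
  pre_arr <- bg + amp_pre * g_pre

  gtv_true <- binary_mask(ellipsoid_mask_arr(w, cc, spec$tumour_radii),
                          spec$spacing, geom$origin)
  pre40_arr <- (pre_arr >= 0.4 * spec$baseline_peak_suv) & gtv_true$data

  # residual position: offset along axis 1 solved so the voxel-counted
  # containment in the baseline 40% region matches the request
  res_mask_at <- function(t_off)
    ellipsoid_mask_arr(w, cc + c(t_off, 0, 0), spec$residual_radii)
  containment_at <- function(t_off) {
    m <- res_mask_at(t_off)
    nm <- sum(m)
    if (nm == 0) return(0) # pushed off the grid: nothing contained
    sum(m & pre40_arr) / nm
  }
  rho <- spec$containment_fraction
  c0 <- containment_at(0)
  if (c0 < rho - 1e-12) {
    # analytic semi-axes of the baseline 40% iso-ellipsoid
    q40 <- -2 * log((0.4 * spec$baseline_peak_suv - bg) / amp_pre)
    r40 <- spec$tumour_radii / 2 * sqrt(max(q40, 0))
    lim <- which.max(spec$residual_radii / r40)
    stop(sprintf(paste0("containment_fraction %.2f is unreachable: the ",
                        "residual region does not fit inside the baseline ",
                        "40%% region (limiting axis %d: residual semi-axis ",
                        "%.1f mm vs 40%%-region semi-axis %.1f mm)"),
                 rho, lim, spec$residual_radii[lim], r40[lim]))
  }
  t_off <- 0
  if (c0 > rho) {
    lo <- 0
    hi <- max(spec$tumour_radii[1], 1) + spec$residual_radii[1] + spec$spacing[1]
    while (containment_at(hi) > rho) hi <- hi * 1.5
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (containment_at(mid) >= rho) lo <- mid else hi <- mid
      if (hi - lo < 1e-3) break
    }
    t_off <- if (abs(containment_at(lo) - rho) <= abs(containment_at(hi) - rho))
      lo else hi
  }
  res_center <- cc + c(t_off, 0, 0)
  residual_true <- binary_mask(res_mask_at(t_off), spec$spacing, geom$origin)
  achieved <- containment_at(t_off)

  # post-treatment anatomy in planning space, then pushed through the
  # ground-truth map phi(x) = cc + s (x - cc) + shift e3 by sampling the
  # analytic pattern at phi^{-1}(y) -- exact, no interpolation
  s <- spec$shrinkage
  px <- cc[1] + (w$x - cc[1]) / s
  py <- cc[2] + (w$y - cc[2]) / s
  pz <- cc[3] + (w$z - spec$caudal_shift - cc[3]) / s
  g_post <- uptake_profile(px, py, pz, res_center, spec$residual_radii)
  if (max(g_post) == 0)
    stop("deformed residual region contains no voxel centers")
  post_arr <- bg + (spec$post_peak_suv - bg) / max(g_post) * g_post

  field_true <- affine_field(geom, scale = s, center = cc,
                             translation = c(0, 0, spec$caudal_shift))

  # CT-like companions: body ellipse at soft-tissue level, tumour slightly
  # denser; post CT carries the same deformation
  fov <- (spec$grid_shape - 1) * spec$spacing
  body_c <- fov / 2
  body_r <- 0.45 * fov
  body <- ellipsoid_mask_arr(w, body_c, body_r)
  pre_ct_arr <- -1000 + 1040 * body + 20 * gtv_true$data
  post_tum <- ((px - cc[1]) / spec$tumour_radii[1])^2 +
    ((py - cc[2]) / spec$tumour_radii[2])^2 +
    ((pz - cc[3]) / spec$tumour_radii[3])^2 <= 1
  post_ct_arr <- -1000 + 1040 * body + 20 * post_tum

  pre_img <- image_volume(pre_arr, spec$spacing, geom$origin)
  post_img <- image_volume(post_arr, spec$spacing, geom$origin)
  if (spec$psf_fwhm > 0) {
    pre_img <- apply_psf_blur(pre_img, spec$psf_fwhm)
    post_img <- apply_psf_blur(post_img, spec$psf_fwhm)
  }
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    nvox <- prod(spec$grid_shape)
    pre_img$data <- pmax(pre_img$data +
      array(stats::rnorm(nvox, 0, spec$noise_sd), spec$grid_shape), 0)
    post_img$data <- pmax(post_img$data +
      array(stats::rnorm(nvox, 0, spec$noise_sd), spec$grid_shape), 0)
  }

  structure(list(
    pre_pet = pre_img, post_pet = post_img,
    pre_ct = image_volume(pre_ct_arr, spec$spacing, geom$origin),
    post_ct = image_volume(post_ct_arr, spec$spacing, geom$origin),
    gtv_true = gtv_true,
    residual_true = residual_true,
    pre40_true = binary_mask(pre40_arr, spec$spacing, geom$origin),
    field_true = field_true,
    achieved_containment = achieved,
    residual_center = res_center,
    spec = spec), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(paste0("<phantom_pair> grid %s, GTV %.1f cm^3, residual %.1f ",
                     "cm^3, containment %.3f (requested %.2f)\n"),
              paste(x$spec$grid_shape, collapse = "x"),
              mask_volume_cc(x$gtv_true), mask_volume_cc(x$residual_true),
              x$achieved_containment, x$spec$containment_fraction))
  invisible(x)
}

#' Write a phantom pair to disk
#'
#' NIfTI volumes for the four scans, uint8 NIfTI for the ground-truth masks,
#' NIfTI per displacement component, plus a JSON sidecar recording the spec,
#' seed and achieved containment.
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(pair$pre_pet, file.path(dir, "pre_pet.nii.gz"))
  write_volume(pair$post_pet, file.path(dir, "post_pet.nii.gz"))
  write_volume(pair$pre_ct, file.path(dir, "pre_ct.nii.gz"))
  write_volume(pair$post_ct, file.path(dir, "post_ct.nii.gz"))
  write_mask(pair$gtv_true, file.path(dir, "gtv_true.nii.gz"))
  write_mask(pair$residual_true, file.path(dir, "residual_true.nii.gz"))
  f <- pair$field_true
  for (comp in c("dx", "dy", "dz"))
    write_volume(image_volume(f[[comp]], f$spacing, f$origin),
                 file.path(dir, sprintf("field_%s.nii.gz", comp)))
  side <- unclass(pair$spec)
  side$achieved_containment <- pair$achieved_containment
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
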