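#' Per-patient pipeline configuration
#'
#' Threshold fractions and regions of interest for a full per-patient run.
#' Baseline fractions default to 40% and 50% of SUVmax; post-treatment
#' fractions to 90/80/70/60% (higher thresholds are needed after treatment
#' because the shrunken, less avid residual suffers more partial-volume
#' underestimation).
#'
#' @param pre_roi,post_roi [elliptical_roi()]s around the tumour on the
#'   baseline and post-treatment scans.
#' @param pre_fractions,post_fractions Fractions of SUVmax in (0, 1].
#' @param keep_component_with_max Passed to [threshold_spec()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(pre_roi, post_roi,
                       pre_fractions = c(0.4, 0.5),
                       post_fractions = c(0.9, 0.8, 0.7, 0.6),
                       keep_component_with_max = TRUE) {
  stopifnot(inherits(pre_roi, "elliptical_roi"),
            inherits(post_roi, "elliptical_roi"))
  chk <- function(f, decreasing) {
    if (length(f) == 0 || any(f <= 0) || any(f > 1))
      stop("threshold fractions must lie in (0, 1]")
    sort(f, decreasing = decreasing)
  }
  structure(list(pre_roi = pre_roi, post_roi = post_roi,
                 pre_fractions = chk(pre_fractions, FALSE),
                 post_fractions = chk(post_fractions, TRUE),
                 keep_component_with_max = isTRUE(keep_component_with_max)),
            class = "run_config")
}

mask_set_name <- function(prefix, fractions)
  sprintf("%s%d", prefix, as.integer(round(fractions * 100)))

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full spatial-overlap pipeline for one patient
#'
#' Chains the analysis stages: SUVmax in each ROI; baseline segmentation at
#' the configured fractions (on the planning grid); post-treatment
#' segmentation on the post-scan grid followed by propagation onto the
#' planning grid through the deformation field; volumes in cm^3; the overlap
#' fraction of every warped post-treatment volume inside every baseline
#' volume; and the GTV coverage of each baseline volume. Errors carry the
#' failing stage name.
#'
#' @param pre_pet,post_pet SUV `image_volume`s (baseline on the planning
#'   grid, post-treatment on its native grid).
#' @param field [deformation_field()] on the planning grid mapping planning
#'   points into the post-scan space (pull-back); use
#'   [identity_field()] to analyse without registration.
#' @param gtv [binary_mask()] on the planning grid.
#' @param config A [run_config()].
#' @return List with `suvmax_pre`, `suvmax_post`, `pre_masks`,
#'   `post_masks_native`, `post_masks_warped` (named mask lists),
#'   `volumes_cc` (named, native grids), `overlap_pct` (matrix, rows =
#'   baseline volumes, cols = warped post volumes), `gtv_coverage_pct`.
#' @export
run_patient <- function(pre_pet, post_pet, field, gtv, config) {
  stopifnot(inherits(config, "run_config"))
  stage("gtv", stopifnot_same_geometry(pre_pet, gtv, "pre PET and GTV"))
  mx_pre <- stage("suv", suv_max_in_roi(pre_pet, config$pre_roi))
  mx_post <- stage("suv", suv_max_in_roi(post_pet, config$post_roi))

  seg <- function(img, roi, f) threshold_segment(img, roi,
    threshold_spec(fraction = f,
                   keep_component_with_max = config$keep_component_with_max))
  pre_names <- mask_set_name("Pre", config$pre_fractions)
  post_names <- mask_set_name("Post", config$post_fractions)
  pre_masks <- stage("segment", stats::setNames(lapply(
    config$pre_fractions, function(f) seg(pre_pet, config$pre_roi, f)),
    pre_names))
  post_native <- stage("segment", stats::setNames(lapply(
    config$post_fractions, function(f) seg(post_pet, config$post_roi, f)),
    post_names))
  post_warped <- stage("register", lapply(post_native, warp_mask, field = field))

  vols <- c(list(GTV = gtv), pre_masks, post_native)
  volumes_cc <- vapply(vols, mask_volume_cc, numeric(1))

  ov <- stage("overlap", vapply(post_warped, function(pm) {
    if (sum(pm$data) == 0) return(rep(NA_real_, length(pre_masks)))
    vapply(pre_masks, overlap_fraction, numeric(1), b = pm)
  }, numeric(length(pre_masks))))
  ov <- matrix(ov, nrow = length(pre_masks),
               dimnames = list(pre_names, post_names))
  cov <- stage("overlap", vapply(pre_masks, gtv_coverage, numeric(1), gtv = gtv))

  list(suvmax_pre = mx_pre$suv_max, suvmax_post = mx_post$suv_max,
       pre_masks = pre_masks, post_masks_native = post_native,
       post_masks_warped = post_warped,
       volumes_cc = volumes_cc, overlap_pct = ov, gtv_coverage_pct = cov)
}

#' Generate a phantom and run the pipeline on it
#'
#' Convenience wrapper used throughout the property tests and the simulation
#' studies: generates the phantom pair, derives generous elliptical ROIs from
#' the known tumour geometry (baseline ROI about the tumour center,
#' post-treatment ROI about the deformed residual center), and runs
#' [run_patient()] with the ground-truth deformation field (or the identity,
#' to quantify what ignoring registration costs).
#'
#' @param spec A [phantom_spec()].
#' @param use_field Apply the ground-truth field (`TRUE`, default) or the
#'   identity field.
#' @param roi_scale ROI semi-axes as a multiple of the tumour radii.
#' @return List with `pair` (the phantom) and `result` (from
#'   [run_patient()]).
#' @export
run_phantom_patient <- function(spec, use_field = TRUE, roi_scale = 1.6) {
  pair <- generate_phantom_pair(spec)
  cc <- spec$tumour_center
  s <- spec$shrinkage
  post_center <- cc + s * (pair$residual_center - cc) +
    c(0, 0, spec$caudal_shift)
  cfg <- run_config(
    pre_roi = elliptical_roi(cc, roi_scale * spec$tumour_radii),
    post_roi = elliptical_roi(post_center, roi_scale * spec$tumour_radii))
  field <- if (use_field) pair$field_true else identity_field(pair$pre_pet)
  list(pair = pair,
       result = run_patient(pair$pre_pet, pair$post_pet, field,
                            pair$gtv_true, cfg))
}
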