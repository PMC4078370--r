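#' PET acquisition metadata
#'
#' Carries the quantities needed for body-weight SUV normalisation plus the
#' scan-time eligibility inputs. Uptake time is recorded for provenance but is
#' not used in any correction: images are assumed to be vendor-reconstructed,
#' decay-corrected activity.
#'
#' @param injected_dose_MBq Injected FDG activity, MBq (> 0).
#' @param body_weight_kg Patient body weight, kg (> 0).
#' @param uptake_time_min Minutes between injection and acquisition start
#'   (clinical protocol here: 90).
#' @param blood_glucose_mmol_l Blood glucose at scan time, mmol/L.
#' @param scan_role `"baseline"` or `"post_crt"`.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_dose_MBq, body_weight_kg,
                             uptake_time_min = 90,
                             blood_glucose_mmol_l = NA_real_,
                             scan_role = c("baseline", "post_crt")) {
  scan_role <- match.arg(scan_role)
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected_dose_MBq must be positive")
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be positive")
  structure(list(injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg,
                 uptake_time_min = uptake_time_min,
                 blood_glucose_mmol_l = blood_glucose_mmol_l,
                 scan_role = scan_role),
            class = "acquisition_meta")
}

#' Axis-aligned elliptical region of interest
#'
#' The ROI a reader draws around the area of increased uptake (excluding liver
#' and kidneys); SUVmax is taken inside it. Axis-aligned in world mm: a voxel
#' center x is inside iff sum(((x - center) / radii)^2) <= 1.
#'
#' @param center Numeric length-3, world mm.
#' @param radii Numeric length-3, semi-axes in mm (> 0).
#' @return An object of class `elliptical_roi`.
#' @export
elliptical_roi <- function(center, radii) {
  center <- as.numeric(center); radii <- as.numeric(radii)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be three finite mm values")
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be three positive mm values")
  structure(list(center = center, radii = radii), class = "elliptical_roi")
}

# logical array: voxel centers inside the ROI ellipsoid
roi_mask_array <- function(vol, roi) {
  w <- grid_world_coords(vol)
  ((w$x - roi$center[1]) / roi$radii[1])^2 +
    ((w$y - roi$center[2]) / roi$radii[2])^2 +
    ((w$z - roi$center[3]) / roi$radii[3])^2 <= 1
}

#' Convert an activity image to SUV
#'
#' Body-weight SUV: `SUV = activity [Bq/ml] * body_weight [g] / injected_dose
#' [Bq]` (tissue density 1 g/ml, so SUV is dimensionless). Negative input
#' voxels (reconstruction artefacts) are clipped to zero; the count of clipped
#' voxels is attached as attribute `"n_clipped"` and reported via `message()`.
#'
#' @param activity An [image_volume()] in Bq/ml.
#' @param meta An [acquisition_meta()].
#' @return An `suv_image` (subclass of `image_volume`) with `meta` attached.
#' @export
to_suv <- function(activity, meta) {
  stopifnot(inherits(activity, "image_volume"), inherits(meta, "acquisition_meta"))
  arr <- activity$data * (meta$body_weight_kg * 1000) /
    (meta$injected_dose_MBq * 1e6)
  n_clipped <- sum(arr < 0)
  if (n_clipped > 0) {
    message(sprintf("to_suv: clipped %d negative voxels to 0", n_clipped))
    arr[arr < 0] <- 0
  }
  out <- image_volume(arr, activity$spacing, activity$origin)
  out$meta <- meta
  attr(out, "n_clipped") <- n_clipped
  class(out) <- c("suv_image", "image_volume")
  out
}

#' Maximum SUV within an elliptical ROI
#'
#' Returns the hottest voxel (SUVmax, not SUVpeak) among voxels whose centers
#' fall inside the ROI. Ties are broken deterministically by the smallest
#' linear (column-major) index.
#'
#' @param img An `image_volume` in SUV units.
#' @param roi An [elliptical_roi()].
#' @return List with `suv_max`, `index` (1-based voxel triple) and
#'   `linear_index`.
#' @export
suv_max_in_roi <- function(img, roi) {
  stopifnot(inherits(img, "image_volume"), inherits(roi, "elliptical_roi"))
  inside <- roi_mask_array(img, roi)
  if (!any(inside)) stop("ROI contains no voxel centers")
  vals <- img$data
  vals[!inside] <- -Inf
  lin <- which.max(vals) # first maximum in column-major order
  list(suv_max = vals[lin],
       index = as.integer(arrayInd(lin, dim(vals))),
       linear_index = as.integer(lin))
}

#' Planned FDG dose from body weight
#'
#' Protocol dose rule: 4 MBq per kg of body weight, capped at 600 MBq.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @return Dose in MBq.
#' @export
planned_dose <- function(weight_kg) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("weight_kg must be positive")
  pmin(4 * weight_kg, 600)
}

# exclusion reasons in the order they are tested; first match wins
eligibility_reasons <- c(
  mCR = "complete metabolic response",
  non_avid = "tumour not FDG avid",
  no_post_scan = "no post-CRT scan",
  diffuse_uptake = "diffuse uptake, not separable from normal tissue",
  glucose = "blood glucose >= 10 mmol/L"
)

#' Scan-pair eligibility for the spatial analysis
#'
#' Applies the exclusion rules in a fixed order, returning the first matching
#' reason: complete metabolic response; non-FDG-avid tumour; missing
#' post-treatment scan; diffuse uptake inseparable from normal tissue; blood
#' glucose at or above 10 mmol/L at either scan.
#'
#' @param record A list (or one-row data.frame) with logical flags
#'   `complete_metabolic_response`, `fdg_avid`, `has_post_scan`,
#'   `uptake_separable` and numeric `glucose_baseline`, `glucose_post`
#'   (mmol/L; `glucose_post` may be NA when no post scan exists).
#' @return List with `included` (logical) and `reason` (`NA` or one of
#'   `"mCR"`, `"non_avid"`, `"no_post_scan"`, `"diffuse_uptake"`, `"glucose"`).
#' @export
check_eligibility <- function(record) {
  record <- as.list(record)
  need <- c("complete_metabolic_response", "fdg_avid", "has_post_scan",
            "uptake_separable", "glucose_baseline", "glucose_post")
  for (f in need)
    if (is.null(record[[f]]) || (f != "glucose_post" && is.na(record[[f]])))
      stop(sprintf("eligibility flag '%s' is missing", f))
  reason <- NA_character_
  if (isTRUE(record$complete_metabolic_response)) reason <- "mCR"
  else if (!isTRUE(record$fdg_avid)) reason <- "non_avid"
  else if (!isTRUE(record$has_post_scan)) reason <- "no_post_scan"
  else if (!isTRUE(record$uptake_separable)) reason <- "diffuse_uptake"
  else {
    glu <- c(record$glucose_baseline, record$glucose_post)
    if (any(glu >= 10, na.rm = TRUE)) reason <- "glucose"
  }
  list(included = is.na(reason), reason = reason)
}
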