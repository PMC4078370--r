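#' Threshold specification for tumour segmentation
#'
#' Either relative (`fraction` of the ROI SUVmax: 0.40/0.50 at baseline,
#' 0.60--0.90 post-treatment) or absolute (a fixed SUV such as 2.5). By
#' default only the 26-connected component containing the SUVmax voxel is
#' kept, so disconnected above-threshold islands (e.g. nearby bowel or renal
#' uptake inside the ROI) are dropped.
#'
#' @param fraction Fraction of SUVmax in (0, 1] (relative mode).
#' @param absolute_suv Absolute SUV threshold (absolute mode).
#' @param keep_component_with_max Keep only the connected component containing
#'   the SUVmax voxel? Default `TRUE`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(fraction = NULL, absolute_suv = NULL,
                           keep_component_with_max = TRUE) {
  if (is.null(fraction) == is.null(absolute_suv))
    stop("give exactly one of 'fraction' or 'absolute_suv'")
  if (!is.null(fraction) && (fraction <= 0 || fraction > 1))
    stop("'fraction' must be in (0, 1]")
  if (!is.null(absolute_suv) && absolute_suv <= 0)
    stop("'absolute_suv' must be positive")
  structure(list(mode = if (is.null(fraction)) "absolute" else "relative",
                 fraction = fraction, absolute_suv = absolute_suv,
                 keep_component_with_max = isTRUE(keep_component_with_max)),
            class = "threshold_spec")
}

# 26-connected component of `mask_arr` containing seed voxel (linear index),
# by frontier expansion over precomputed neighbour offsets.
component_containing <- function(mask_arr, seed_lin) {
  d <- dim(mask_arr)
  if (!mask_arr[seed_lin]) return(array(FALSE, d))
  # guard band so linear-index neighbour arithmetic never wraps across faces
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask_arr
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lin_off <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  seed_idx <- arrayInd(seed_lin, d) + 1L
  seed_pad <- seed_idx[1] + (seed_idx[2] - 1L) * dp[1] +
    (seed_idx[3] - 1L) * dp[1] * dp[2]
  comp <- array(FALSE, dp)
  comp[seed_pad] <- TRUE
  frontier <- seed_pad
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, lin_off, "+")))
    nb <- nb[pad[nb] & !comp[nb]]
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

#' Segment a tumour subvolume by SUV thresholding
#'
#' A voxel belongs to the mask iff its center lies inside the ROI and its SUV
#' is at or above the threshold (`fraction * SUVmax(ROI)` in relative mode, or
#' `absolute_suv`). The threshold is inclusive, so `fraction = 1` yields
#' exactly the SUVmax voxel (up to ties). With `keep_component_with_max` only
#' the 26-connected component containing the SUVmax voxel is retained, which
#' preserves nesting across fractions.
#'
#' @param img An `image_volume` in SUV units.
#' @param roi An [elliptical_roi()].
#' @param spec A [threshold_spec()].
#' @return A [binary_mask()] on the image grid.
#' @export
threshold_segment <- function(img, roi, spec) {
  stopifnot(inherits(img, "image_volume"), inherits(spec, "threshold_spec"))
  mx <- suv_max_in_roi(img, roi)
  if (spec$mode == "relative") {
    if (mx$suv_max <= 0)
      stop("non-avid: SUVmax within the ROI is not positive; ",
           "relative thresholding is undefined")
    thr <- spec$fraction * mx$suv_max
  } else {
    thr <- spec$absolute_suv
  }
  inside <- roi_mask_array(img, roi)
  m <- inside & (img$data >= thr)
  if (spec$keep_component_with_max && any(m)) {
    # in absolute mode the SUVmax voxel can fall below the threshold;
    # then the mask is kept as-is (no anchor component exists)
    if (m[mx$linear_index]) m <- component_containing(m, mx$linear_index)
  }
  binary_mask(m, img$spacing, img$origin)
}
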