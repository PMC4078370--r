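#' Overlap fraction of a reference volume inside another volume
#'
#' `overlap_fraction(a, b)` is the percentage of volume `b` contained in `a`:
#' `100 * |a intersect b| / |b|`, by voxel counts on a common grid. This is
#' the statistic used to ask how much of a post-treatment uptake volume falls
#' inside a baseline subvolume (the post-treatment volume is the reference
#' `b`). It is 100 iff `b` is voxelwise contained in `a` and 0 iff they are
#' disjoint. Values are returned at full precision; round only for tables
#' (see [round_half_up()]).
#'
#' @param a,b [binary_mask()]s on the same grid; `b` must be non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stopifnot_same_geometry(a, b, "masks")
  nb <- sum(b$data)
  if (nb == 0) stop("empty reference volume")
  100 * sum(a$data & b$data) / nb
}

#' Coverage of the gross tumour volume by a PET subvolume
#'
#' `100 * |pre intersect gtv| / |gtv|`: the percentage of the clinician-drawn
#' GTV covered by a baseline uptake subvolume. A boost volume covering only
#' part of the GTV is what makes selective dose escalation attractive.
#'
#' @param pre,gtv [binary_mask()]s on the same grid; `gtv` non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
gtv_coverage <- function(pre, gtv) {
  tryCatch(overlap_fraction(pre, gtv),
           error = function(e) stop("empty GTV", call. = FALSE))
}

#' Dice similarity coefficient
#'
#' `200 * |a intersect b| / (|a| + |b|)`; used as a cross-check consistent
#' with the directional overlap fractions (same intersection count).
#'
#' @inheritParams overlap_fraction
#' @return Percentage in `[0, 100]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_geometry(a, b, "masks")
  denom <- sum(a$data) + sum(b$data)
  if (denom == 0) stop("both masks empty")
  200 * sum(a$data & b$data) / denom
}

#' Cohort summary statistics
#'
#' Arithmetic mean, extrema and median of a set of per-patient values. The
#' median uses the midpoint-of-central-values convention for even n (the
#' default sample median).
#'
#' @param values Non-empty numeric vector (NA not allowed).
#' @return Named list `mean`, `min`, `max`, `median` at full precision.
#' @export
cohort_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("'values' must be non-empty with no NA")
  list(mean = mean(values), min = min(values), max = max(values),
       median = stats::median(values))
}

#' Two-tailed paired t-test
#'
#' For paired values the statistic is `t = mean(d) / (sd(d) / sqrt(n))` with
#' `d = pre - post` and `df = n - 1`; the two-sided p-value comes from the t
#' distribution. Used here for the within-patient change in SUVmax across
#' chemoradiotherapy.
#'
#' @param pre,post Equal-length numeric vectors, `n >= 2`.
#' @return Named list `t`, `df`, `p`.
#' @export
paired_t_test <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) stop("'pre' and 'post' differ in length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- pre - post
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: t statistic undefined")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE))
}

#' Round half away from zero
#'
#' Table-style rounding (0.05 -> 0.1 at one decimal), unlike base R's
#' round-half-to-even. Applied only when formatting results for reports.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
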