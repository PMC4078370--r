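# Brute-force scalar-loop oracles, kept independent of the vectorized
# implementations they check.

# per-voxel SUV conversion by explicit looping
oracle_to_suv <- function(activity_arr, weight_kg, dose_MBq) {
  d <- dim(activity_arr)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- activity_arr[i, j, k] * (weight_kg * 1000) / (dose_MBq * 1e6)
    out[i, j, k] <- max(v, 0)
  }
  out
}

# exhaustive in-ROI maximum with first-linear-index tie-break
oracle_suv_max <- function(vol, roi) {
  d <- dim(vol$data)
  best <- -Inf; best_lin <- NA_integer_
  lin <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    lin <- lin + 1L
    x <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    if (sum(((x - roi$center) / roi$radii)^2) <= 1) {
      v <- vol$data[i, j, k]
      if (v > best) { best <- v; best_lin <- lin }
    }
  }
  # column-major linear index order equals i-fastest scan order above
  list(suv_max = best, linear_index = best_lin)
}

# voxel-count overlap percent by explicit looping
oracle_overlap <- function(a, b) {
  d <- dim(a$data)
  n_b <- 0L; n_ab <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (b$data[i, j, k]) {
      n_b <- n_b + 1L
      if (a$data[i, j, k]) n_ab <- n_ab + 1L
    }
  }
  100 * n_ab / n_b
}

# small phantom spec used where full-size runs would be wasteful
small_spec <- function(...) {
  args <- list(grid_shape = c(40, 40, 40), spacing = c(2.5, 2.5, 2.5),
               tumour_radii = c(18, 16, 14), residual_radii = c(10, 8, 7))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# uniform test volume helper
uvol <- function(value, d = c(8, 8, 8), spacing = c(1, 1, 1)) {
  image_volume(array(value, d), spacing)
}
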