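#' Dense deformation field on a fixed grid
#'
#' Per-voxel displacement vectors (mm) defined on the fixed (radiotherapy
#' planning) grid, in the pull-back convention: the warped value at fixed
#' point `x` is the moving image sampled at `x + d(x)`. This matches how a
#' verified CT-CT deformation is applied to PET data to propagate contours
#' onto the planning scan.
#'
#' @param dx,dy,dz 3D arrays of displacement components, mm.
#' @inheritParams image_volume
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, dz, spacing, origin = c(0, 0, 0)) {
  dx <- as.array(dx); dy <- as.array(dy); dz <- as.array(dz)
  if (!identical(dim(dx), dim(dy)) || !identical(dim(dx), dim(dz)) ||
      length(dim(dx)) != 3L)
    stop("dx, dy, dz must be 3D arrays of identical dimension")
  g <- image_volume(dx, spacing, origin)
  structure(list(dx = dx, dy = dy, dz = dz,
                 spacing = g$spacing, origin = g$origin),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  cat(sprintf("<deformation_field> %s voxels, max |d| = %.2f mm\n",
              paste(dim(x$dx), collapse = "x"), max(mag)))
  invisible(x)
}

#' Identity and affine deformation fields
#'
#' `identity_field()` is the zero displacement on a reference grid.
#' `affine_field()` encodes, in pull-back form, the map
#' `x -> center + scale * (x - center) + translation`, i.e.
#' `d(x) = (scale - 1) * (x - center) + translation`. With `scale < 1` the
#' warped mask grows by `1 / scale^3` (the moving anatomy shrank).
#'
#' @param ref An `image_volume` (or mask/field) defining the grid.
#' @param scale Scalar or length-3 linear factor (> 0).
#' @param center World point (mm) the scaling is taken about.
#' @param translation Length-3 translation, mm.
#' @return A [deformation_field()].
#' @export
identity_field <- function(ref) {
  z <- array(0, dim(if (inherits(ref, "deformation_field")) ref$dx else ref$data))
  deformation_field(z, z, z, ref$spacing, ref$origin)
}

#' @rdname identity_field
#' @export
affine_field <- function(ref, scale = 1, center = c(0, 0, 0),
                         translation = c(0, 0, 0)) {
  scale <- rep_len(as.numeric(scale), 3L)
  if (any(scale <= 0)) stop("'scale' must be positive")
  w <- grid_world_coords(ref)
  deformation_field(
    (scale[1] - 1) * (w$x - center[1]) + translation[1],
    (scale[2] - 1) * (w$y - center[2]) + translation[2],
    (scale[3] - 1) * (w$z - center[3]) + translation[3],
    ref$spacing, ref$origin)
}

# Vectorized trilinear interpolation of a 3D array at fractional 1-based voxel
# coordinates (n x 3 matrix). Points outside the grid get `outside`.
trilinear <- function(arr, idx, outside = 0, clamp = FALSE) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  if (clamp) {
    x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
    z <- pmin(pmax(z, 1), d[3])
  }
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, nrow(idx))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  i000 <- x0 + (y0 - 1) * d[1] + (z0 - 1) * d[1] * d[2]
  i100 <- i000 + 1; i010 <- i000 + d[1]; i110 <- i010 + 1
  i001 <- i000 + d[1] * d[2]; i101 <- i001 + 1
  i011 <- i001 + d[1]; i111 <- i011 + 1
  v <- (arr[i000] * (1 - fx) + arr[i100] * fx) * (1 - fy) * (1 - fz) +
       (arr[i010] * (1 - fx) + arr[i110] * fx) * fy * (1 - fz) +
       (arr[i001] * (1 - fx) + arr[i101] * fx) * (1 - fy) * fz +
       (arr[i011] * (1 - fx) + arr[i111] * fx) * fy * fz
  out[ok] <- v
  out
}

# sample a moving volume at fixed-grid points displaced by the field
resample_by_field <- function(moving_arr, moving_geom, field, outside = 0) {
  w <- grid_world_coords(field_as_volume(field))
  pts <- cbind(as.vector(w$x) + as.vector(field$dx),
               as.vector(w$y) + as.vector(field$dy),
               as.vector(w$z) + as.vector(field$dz))
  idx <- world_to_index(moving_geom, pts)
  array(trilinear(moving_arr, idx, outside), dim(field$dx))
}

field_as_volume <- function(field) {
  image_volume(field$dx, field$spacing, field$origin)
}

#' Warp an image through a deformation field
#'
#' Resamples the moving image at `x + d(x)` for every fixed-grid voxel center
#' `x`, with trilinear interpolation; samples falling outside the moving grid
#' take `outside`.
#'
#' @param img Moving `image_volume`.
#' @param field A [deformation_field()] on the fixed grid.
#' @param outside Value for out-of-grid samples.
#' @return An `image_volume` on the fixed grid.
#' @export
warp_image <- function(img, field, outside = 0) {
  stopifnot(inherits(img, "image_volume"), inherits(field, "deformation_field"))
  image_volume(resample_by_field(img$data, img, field, outside),
               field$spacing, field$origin)
}

#' Propagate a binary mask through a deformation field
#'
#' The mask is cast to a 0/1 scalar field, resampled at `x + d(x)` with
#' trilinear interpolation, and re-binarized at 0.5. Out-of-grid samples are
#' background. Float resampling (rather than nearest-neighbour) gives smoother
#' volume behaviour under shrinkage/expansion.
#'
#' @param mask Moving [binary_mask()].
#' @param field A [deformation_field()] on the fixed grid; for same-grid
#'   propagation the mask and field grids coincide.
#' @return A [binary_mask()] on the fixed grid.
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "binary_mask"), inherits(field, "deformation_field"))
  vals <- resample_by_field(array(as.numeric(mask$data), dim(mask$data)),
                            mask, field, outside = 0)
  binary_mask(vals >= 0.5, field$spacing, field$origin)
}

#' Validate a deformation field
#'
#' Computes the Jacobian determinant of the map `x + d(x)` by central finite
#' differences (one-sided at grid faces) and summarises displacement
#' magnitudes. A field folds (is not invertible) where the determinant is
#' non-positive.
#'
#' @param field A [deformation_field()].
#' @return List with `ok`, `min_jacobian`, `max_jacobian`,
#'   `max_displacement_mm`, `folding_fraction`.
#' @export
validate_field <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  d <- dim(field$dx)
  grad <- function(arr, axis) {
    n <- d[axis]; h <- field$spacing[axis]
    if (n < 2L) return(array(0, d))
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idx_p - idx_m) * h
    sel <- function(i) switch(axis,
                              arr[i, , , drop = FALSE],
                              arr[, i, , drop = FALSE],
                              arr[, , i, drop = FALSE])
    g <- sel(idx_p) - sel(idx_m)
    sweep(g, axis, denom, "/")
  }
  # J = I + grad d (rows: output component, cols: derivative direction)
  j11 <- 1 + grad(field$dx, 1L); j12 <- grad(field$dx, 2L); j13 <- grad(field$dx, 3L)
  j21 <- grad(field$dy, 1L); j22 <- 1 + grad(field$dy, 2L); j23 <- grad(field$dy, 3L)
  j31 <- grad(field$dz, 1L); j32 <- grad(field$dz, 2L); j33 <- 1 + grad(field$dz, 3L)
  det <- j11 * (j22 * j33 - j23 * j32) -
         j12 * (j21 * j33 - j23 * j31) +
         j13 * (j21 * j32 - j22 * j31)
  mag <- sqrt(field$dx^2 + field$dy^2 + field$dz^2)
  list(ok = all(det > 0),
       min_jacobian = min(det),
       max_jacobian = max(det),
       max_displacement_mm = max(mag),
       folding_fraction = mean(det <= 0))
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration for the inverse displacement:
#' `v_{k+1}(x) = -d(x + v_k(x))`, starting from `v_0 = -d`. Converges for
#' smooth, fold-free fields of moderate magnitude.
#'
#' @param field A [deformation_field()].
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max update, mm.
#' @return A [deformation_field()] approximating the inverse map.
#' @export
invert_field <- function(field, max_iter = 50L, tol = 1e-3) {
  stopifnot(inherits(field, "deformation_field"))
  geom <- field_as_volume(field)
  w <- grid_world_coords(geom)
  wx <- as.vector(w$x); wy <- as.vector(w$y); wz <- as.vector(w$z)
  vx <- -as.vector(field$dx); vy <- -as.vector(field$dy); vz <- -as.vector(field$dz)
  for (it in seq_len(max_iter)) {
    # clamped sampling: displacements are extended by their border values so
    # points mapped outside the grid still receive a sensible update
    idx <- world_to_index(geom, cbind(wx + vx, wy + vy, wz + vz))
    nx <- -trilinear(field$dx, idx, clamp = TRUE)
    ny <- -trilinear(field$dy, idx, clamp = TRUE)
    nz <- -trilinear(field$dz, idx, clamp = TRUE)
    delta <- max(abs(nx - vx), abs(ny - vy), abs(nz - vz))
    vx <- nx; vy <- ny; vz <- nz
    if (delta < tol) break
  }
  deformation_field(array(vx, dim(field$dx)), array(vy, dim(field$dx)),
                    array(vz, dim(field$dx)), field$spacing, field$origin)
}

#' Rigid (translation-only) alignment by cross-correlation search
#'
#' Finds the translation `t` (mm) maximizing the normalized cross-correlation
#' between the fixed image and the moving image sampled at `x + t`
#' (pull-back, consistent with [deformation_field()]). The search is
#' coarse-to-fine: exhaustive over integer-voxel offsets within
#' `search_mm`, then local refinement at 1/2 and 1/4 voxel steps. Rotation is
#' fixed at identity: patients are scanned immobilised in the treatment
#' position, so residual misalignment is dominated by translation. Ties are
#' broken by the smaller translation norm, then lexicographically.
#'
#' @param moving,fixed `image_volume`s on grids with equal spacing.
#' @param search_mm Half-width of the search range per axis, mm.
#' @return List with `translation_mm` and `ncc` (the attained correlation).
#' @export
rigid_align <- function(moving, fixed, search_mm = 10) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  if (stats::sd(fixed$data) == 0 || stats::sd(moving$data) == 0)
    stop("degenerate (constant) image: cross-correlation undefined")
  ncc_at <- function(t_mm) {
    w <- grid_world_coords(fixed)
    pts <- cbind(as.vector(w$x) + t_mm[1], as.vector(w$y) + t_mm[2],
                 as.vector(w$z) + t_mm[3])
    idx <- world_to_index(moving, pts)
    d <- dim(moving$data)
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (sum(ok) < 8) return(-Inf)
    mv <- trilinear(moving$data, idx[ok, , drop = FALSE])
    fv <- as.vector(fixed$data)[ok]
    if (stats::sd(mv) == 0 || stats::sd(fv) == 0) return(-Inf)
    stats::cor(mv, fv)
  }
  best_of <- function(cands) {
    sc <- vapply(cands, ncc_at, numeric(1))
    top <- which(sc > max(sc) - 1e-12)
    if (length(top) > 1L) {
      nrm <- vapply(cands[top], function(t) sum(t^2), numeric(1))
      top <- top[nrm < min(nrm) + 1e-12]
      if (length(top) > 1L) {
        ord <- do.call(order, as.data.frame(do.call(rbind, cands[top])))
        top <- top[ord[1L]]
      }
    }
    list(t = cands[[top[1L]]], ncc = max(sc))
  }
  sp <- fixed$spacing
  steps <- lapply(1:3, function(a) {
    k <- floor(search_mm / sp[a])
    (-k:k) * sp[a]
  })
  cand <- expand.grid(steps[[1]], steps[[2]], steps[[3]])
  best <- best_of(lapply(seq_len(nrow(cand)), function(i) as.numeric(cand[i, ])))
  for (frac in c(0.5, 0.25)) {
    d <- expand.grid((-1:1) * frac * sp[1], (-1:1) * frac * sp[2],
                     (-1:1) * frac * sp[3])
    cands <- lapply(seq_len(nrow(d)), function(i) best$t + as.numeric(d[i, ]))
    best <- best_of(cands)
  }
  list(translation_mm = best$t, ncc = best$ncc)
}
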