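#' 3D image volume with physical geometry
#'
#' Container for a scalar 3D grid (PET activity, SUV, or CT) together with its
#' voxel spacing and origin in mm. World coordinates of the voxel with 1-based
#' index `(i, j, k)` are `origin + (c(i, j, k) - 1) * spacing`; axes are
#' axis-aligned (no direction matrix). By convention the third grid axis is
#' cranio-caudal with increasing index pointing inferior (caudal).
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary mask sharing an image geometry
#'
#' @param data Logical (or coercible) 3D array.
#' @inheritParams image_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  v <- image_volume(array(FALSE, dim(data)), spacing, origin)
  v$data <- data
  class(v) <- c("binary_mask", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  if (inherits(x, "binary_mask"))
    cat(sprintf("  %d foreground voxels (%.1f cm^3)\n",
                sum(x$data), mask_volume_cc(x)))
  else
    cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("%s are not on the same grid (dim/spacing/origin differ)", what))
  invisible(TRUE)
}

# world coordinates (mm) of all voxel centers along one axis
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

# 3 arrays of world coordinates, each of full grid dimension
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  x <- axis_coords(vol, 1L); y <- axis_coords(vol, 2L); z <- axis_coords(vol, 3L)
  list(
    x = array(rep(x, times = d[2] * d[3]), d),
    y = array(rep(rep(y, each = d[1]), times = d[3]), d),
    z = array(rep(z, each = d[1] * d[2]), d)
  )
}

# continuous (1-based, fractional) voxel index for world points; columns x,y,z
world_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/") + 1
}

#' Mask volume in cubic centimetres
#'
#' Voxel-counting volume: number of foreground voxels times the voxel volume.
#'
#' @param mask A [binary_mask()].
#' @return Volume in cm^3 (numeric scalar, full precision; round at reporting).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over **RNifti**. Masks are written as uint8 and read back as
#' logical via `read_mask()`. Only spacing and origin of the stored geometry
#' are used; the grid is assumed axis-aligned.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol,mask Object to write.
#' @return `read_volume()` an `image_volume`; `read_mask()` a `binary_mask`;
#'   the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  sp <- RNifti::pixdim(img)[1:3]
  org <- as.numeric(RNifti::xform(img)[1:3, 4])
  image_volume(arr, sp, org)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data > 0.5, v$spacing, v$origin)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- image_volume(array(as.integer(mask$data), dim(mask$data)),
                    mask$spacing, mask$origin)
  write_volume(v, path)
}
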