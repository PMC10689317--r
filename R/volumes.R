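#' Image volume container
#'
#' A minimal carrier for a 3-D scalar image: a numeric array plus voxel
#' spacing in millimetres. Used for MR-like volumes, binary ROI masks and
#' pharmacokinetic parameter maps alike.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3 voxel spacing (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite numbers.")
  }
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x ")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

as_volume_array <- function(x) {
  if (inherits(x, "image_volume")) x$data else x
}

#' Ellipsoidal binary mask
#'
#' Builds a binary ROI mask of an axis-aligned ellipsoid centred in a volume
#' grid, the tumour stand-in used by the phantom generator.
#'
#' @param dim integer length-3 grid dimensions.
#' @param semiaxes numeric length-3 semi-axes in voxels.
#' @param center optional centre (defaults to the grid centre).
#' @return Integer 0/1 array of dimension `dim`.
#' @export
ellipsoid_mask <- function(dim, semiaxes, center = (dim + 1) / 2) {
  if (any(semiaxes <= 0)) abort("semi-axes must be positive")
  if (any(center - semiaxes < 1) || any(center + semiaxes > dim)) {
    abort("ROI ellipsoid does not fit inside the volume grid")
  }
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  r2 <- ((g$x - center[1]) / semiaxes[1])^2 +
    ((g$y - center[2]) / semiaxes[2])^2 +
    ((g$z - center[3]) / semiaxes[3])^2
  array(as.integer(r2 <= 1), dim)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry voxel spacing through the `image_volume` container.
#'
#' @param vol an `image_volume` (or bare array, spacing 1 mm assumed).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   an `image_volume`.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "image_volume")) vol <- image_volume(vol)
  img <- RNifti::asNifti(vol$data, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- c(RNifti::pixdim(img), 1, 1)[seq_len(3)]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_volume(arr, spacing = spacing)
}

# Gaussian smoothing by separable circular convolution along each axis.
# sigma in voxels; sigma = 0 returns the input unchanged.
smooth_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- convolve_axis(arr, k, axis)
  arr
}

# circular (periodic) convolution of a 3-D array along one axis;
# kernel is assumed centred (odd length)
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    sh <- j - 1L - half
    idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
    out <- out + kernel[j] * switch(axis,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE]
    )
  }
  out
}
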