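#' Calibrated single-channel image
#'
#' Container for an 8- or 16-bit grayscale fluorescence image. Pixels are
#' stored as a numeric matrix indexed `[row, col]` (1-based, the R
#' convention); intensities must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth Either 8 or 16.
#' @param calibration Optional micrometers per pixel (strictly positive).
#' @return An object of class `oir_image` with fields `pixels`, `bit_depth`
#'   and `calibration`.
#' @export
oir_image <- function(pixels, bit_depth = 8L, calibration = NULL) {
  if (!is.matrix(pixels) || length(pixels) < 1L)
    abort_oir("'pixels' must be a non-empty matrix", "oir_invalid_image")
  if (!bit_depth %in% c(8L, 16L))
    abort_oir("bit_depth must be 8 or 16", "oir_invalid_image")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    abort_oir(
      sprintf("intensities must lie in [0, %d] and contain no NA", maxval),
      "oir_invalid_image")
  if (!is.null(calibration)) {
    if (!is.numeric(calibration) || length(calibration) != 1L ||
        !is.finite(calibration) || calibration <= 0)
      abort_oir("calibration (um/pixel) must be a positive scalar",
                "oir_invalid_image")
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         calibration = calibration),
    class = "oir_image")
}

#' @export
dim.oir_image <- function(x) dim(x$pixels)

#' @export
as.matrix.oir_image <- function(x, ...) x$pixels

#' @export
print.oir_image <- function(x, ...) {
  cal <- if (is.null(x$calibration)) "uncalibrated"
         else sprintf("%.4g um/px", x$calibration)
  cat(sprintf("<oir_image> %d x %d, %d-bit, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, cal))
  invisible(x)
}

as_oir_image <- function(x, bit_depth = 8L, calibration = NULL) {
  if (inherits(x, "oir_image")) x
  else oir_image(x, bit_depth = bit_depth, calibration = calibration)
}

#' Calibrated fluorescence z-stack
#'
#' An ordered pile of equally shaped grayscale slices with voxel dimensions
#' in micrometers. The default z-spacing of 1.5 um matches confocal serial
#' sectioning through choroidal lesions.
#'
#' @param slices A list of matrices (or a 3D array `[row, col, z]`).
#' @param dx,dy In-plane micrometers per pixel.
#' @param dz Micrometers per z-step (default 1.5).
#' @param bit_depth Either 8 or 16.
#' @return An object of class `oir_stack` with a 3D `voxels` array and the
#'   voxel dimensions.
#' @export
oir_stack <- function(slices, dx = 1, dy = 1, dz = 1.5, bit_depth = 8L) {
  if (is.list(slices)) {
    if (length(slices) < 1L)
      abort_oir("stack needs at least one slice", "oir_invalid_stack")
    shp <- dim(slices[[1L]])
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
      abort_oir("all slices must share the same shape", "oir_invalid_stack")
    voxels <- array(unlist(slices, use.names = FALSE),
                    dim = c(shp, length(slices)))
  } else if (is.array(slices) && length(dim(slices)) == 3L) {
    voxels <- slices
  } else {
    abort_oir("'slices' must be a list of matrices or a 3D array",
              "oir_invalid_stack")
  }
  if (any(c(dx, dy, dz) <= 0) || !all(is.finite(c(dx, dy, dz))))
    abort_oir("voxel dimensions dx, dy, dz must be positive",
              "oir_invalid_stack")
  maxval <- 2^bit_depth - 1
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > maxval)
    abort_oir("voxel intensities out of range for bit depth",
              "oir_invalid_stack")
  structure(
    list(voxels = voxels, dx = dx, dy = dy, dz = dz,
         bit_depth = as.integer(bit_depth)),
    class = "oir_stack")
}

#' @export
dim.oir_stack <- function(x) dim(x$voxels)

#' @export
print.oir_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<oir_stack> %d x %d x %d slices, voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$dx, x$dy, x$dz))
  invisible(x)
}
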