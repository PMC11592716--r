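# 3D image volumes and segmentation masks with physical geometry, plus NIfTI
# I/O through RNifti. Geometry is deliberately simple: axis-aligned, voxel
# (i,j,k) (1-based) has its center at origin + (i - 0.5) * spacing.

#' Create an image volume
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing Voxel spacing in mm, length-3, strictly positive.
#' @param origin World position (mm) of the volume corner (default 0,0,0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(0.5, 0.5, 3), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three strictly positive numbers (mm)")
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "), " voxels @ ",
      paste(format(x$spacing), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Create a segmentation mask sharing an image volume's geometry
#'
#' @param data 3D logical/0-1 array.
#' @param spacing,origin Geometry, as for \code{\link{image_volume}}.
#' @return An object of class \code{segmentation_mask}.
#' @export
segmentation_mask <- function(data, spacing = c(0.5, 0.5, 3),
                              origin = c(0, 0, 0)) {
  vol <- image_volume(array(as.logical(data), dim(data)), spacing, origin)
  class(vol) <- c("segmentation_mask", "image_volume")
  vol
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " labeled\n", sep = "")
  invisible(x)
}

.same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as uint8 with 1 = lesion. Spacing goes into pixdim and the
#' origin into the sform translation.
#'
#' @param vol An \code{image_volume} or \code{segmentation_mask}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (inherits(vol, "segmentation_mask")) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(vol, "segmentation_mask"))
                       "uint8" else "float")
  invisible(path)
}

#' Read a NIfTI file as an image volume or mask
#'
#' @param path NIfTI file path.
#' @param mask Read as a \code{segmentation_mask} (voxels > 0 are lesion)?
#' @return An \code{image_volume} or \code{segmentation_mask}.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (mask) segmentation_mask(arr > 0, sp, orig)
  else image_volume(arr, sp, orig)
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b \code{segmentation_mask} objects on the same geometry.
#' @return Dice coefficient in [0, 1]; \code{NaN} if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) stop("mask geometries differ")
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}
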