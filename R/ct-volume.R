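#' CT volume container
#'
#' A light container for a 3D CT-like grid in Hounsfield units (HU) with
#' voxel spacing and an acquisition day. Axis order is (z, y, x) and spacing
#' is millimetres per voxel along the same axes.
#'
#' @param data 3D numeric array of HU values, axis order (z, y, x).
#' @param spacing numeric length-3, mm per voxel along (z, y, x).
#' @param day acquisition day (days since the patient's baseline scan).
#'
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(-850, c(4, 4, 4)), spacing = c(1, 1, 1), day = 0)
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), day = 0) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm per voxel, z/y/x)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, day = as.numeric(day)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %s voxels, spacing %s mm, day %g, HU range [%.0f, %.0f]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    x$day, min(x$data), max(x$data)
  ))
  invisible(x)
}

voxel_volume_mm3 <- function(spacing) prod(spacing)

#' Read / write volumes and masks as NIfTI
#'
#' Voxel spacing is carried in the NIfTI affine (diagonal, mm); masks are
#' written as 0/1 integers. The acquisition day is stored separately (CSV),
#' not in the NIfTI header.
#'
#' @param x a `ct_volume` or a logical/integer 3D mask array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing for `write_mask_nifti`.
#' @return `read_volume_nifti` returns a `ct_volume` (day 0);
#'   `read_mask_nifti` a logical array with a `spacing` attribute.
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "ct_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim(img)), spacing = sp, day = 0)
}

#' @rdname write_volume_nifti
#' @export
write_mask_nifti <- function(x, path, spacing = attr(x, "spacing") %||% c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(x), dim(x)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img) > 0.5, dim(img))
  attr(m, "spacing") <- RNifti::pixdim(img)[1:3]
  m
}
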