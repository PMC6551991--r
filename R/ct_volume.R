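#' CT volume container
#'
#' A 3D scalar grid in Hounsfield units with voxel spacing and a voxel-to-world
#' affine.  World coordinates (mm) of 0-based voxel index `v` are
#' `affine %*% c(v, 1)`; the default affine is diagonal in the spacing with the
#' origin at voxel (0,0,0).  Axes follow a fixed right-handed convention:
#' +x image-right, +y posterior, +z superior.
#'
#' @param data numeric 3D array of attenuation values (HU).
#' @param spacing numeric length-3 voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, affine = NULL) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  if (any(!is.finite(data))) stop("CT data must be finite")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    stopifnot(all(dim(affine) == c(4, 4)))
    if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  }
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Read / write volumes as NIfTI-1
#'
#' Volumes are exchanged as NIfTI-1 files (optionally gzipped); masks are
#' written as uint8.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param x a `ct_volume`, or a logical/numeric array with a `spacing`
#'   attribute for `write_mask_nifti`.
#' @return `read_ct_volume` returns a `ct_volume`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img)[1:3])
  if (length(dim(img)) > 3) dim(arr) <- dim(img)[1:3]
  ct_volume(arr, spacing)
}

#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ct_volume
#' @param spacing voxel spacing used when `x` is a plain mask array.
#' @export
write_mask_nifti <- function(x, path, spacing) {
  arr <- array(as.integer(x), dim = dim(x))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
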