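# Volumetric pseudo-Z image container and NIfTI-1 I/O.

#' Construct a power volume
#'
#' A power volume is a 3D grid of beamformer pseudo-Z power values
#' together with a 4x4 affine mapping 0-based voxel indices to
#' millimetre coordinates (NIfTI convention; here Talairach mm).
#'
#' @param values 3D numeric array of pseudo-Z values.
#' @param affine 4x4 numeric matrix; last row `(0, 0, 0, 1)`; the upper
#'   3x4 block maps homogeneous 0-based voxel indices to mm.
#' @return A list of class `"power_volume"` with elements `values`,
#'   `affine` and `voxel_mm` (column norms of the linear part).
#' @export
power_volume <- function(values, affine) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("power volume values must be a 3D array; got ",
         length(dim(values)), " dimension(s)", call. = FALSE)
  affine <- unclass(as.matrix(affine))
  attributes(affine)[setdiff(names(attributes(affine)), "dim")] <- NULL
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("degenerate affine: determinant is (numerically) zero",
         call. = FALSE)
  structure(list(
    values = values,
    affine = affine,
    voxel_mm = sqrt(colSums(affine[1:3, 1:3]^2))
  ), class = "power_volume")
}

#' Read a pseudo-Z volume from NIfTI
#'
#' @param path Path to a NIfTI-1 file holding a 3D image.
#' @return A [power_volume()] with the image values and the voxel-to-mm
#'   affine taken from the file's (s/q)form.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D", call. = FALSE)
  power_volume(array(as.numeric(img), dim = d), RNifti::xform(img))
}

#' Write a pseudo-Z volume to NIfTI
#'
#' Values are stored as 64-bit floats so that write/read round-trips are
#' exact; the affine is stored in the sform.
#'
#' @param volume A [power_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "power_volume"))
  img <- RNifti::asNifti(volume$values, datatype = "double")
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map 0-based voxel indices to millimetres through an affine
#'
#' @param idx0 n x 3 matrix of 0-based voxel indices (may be fractional).
#' @param affine 4x4 voxel-to-mm affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(idx0, affine) {
  idx0 <- matrix(as.numeric(idx0), ncol = 3)
  t(affine %*% rbind(t(idx0), 1))[, 1:3, drop = FALSE]
}

#' @export
print.power_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("pseudo-Z power volume: %d x %d x %d voxels (%s mm)\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_mm, 3), collapse = " x ")))
  cat(sprintf("  value range: [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}
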