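# Extraction of band-thresholded local power maxima from pseudo-Z
# volumes, and pooling of peaks across conditions and bands.

#' Extract thresholded local maxima from a pseudo-Z volume
#'
#' A voxel is a peak when its value reaches the band's pseudo-Z cutoff
#' and is strictly greater than all of its 26 face/edge/corner
#' neighbours (boundary voxels are compared against the neighbours that
#' exist). Strict inequality means plateau voxels are never peaks, so a
#' flat region cannot spawn spurious detections. Peak locations are the
#' voxel centres mapped through the volume's affine.
#'
#' @param volume A [power_volume()].
#' @param band Frequency band label (one of [band_levels()]).
#' @param thresholds Named numeric vector of per-band pseudo-Z cutoffs
#'   (default [default_band_thresholds()]).
#' @param subject,condition Labels stamped on the returned peaks.
#' @return A `"peak_table"` data.frame, one row per peak, ordered by
#'   voxel column-major index.
#' @export
extract_local_maxima <- function(volume, band,
                                 thresholds = default_band_thresholds(),
                                 subject = "s1", condition = "c1") {
  stopifnot(inherits(volume, "power_volume"))
  if (!band %in% names(thresholds))
    stop("no threshold configured for band '", band, "'", call. = FALSE)
  v <- volume$values
  if (any(!is.finite(v)))
    stop("volume contains non-finite values", call. = FALSE)
  thr <- thresholds[[band]]
  d <- dim(v)

  # pad with -Inf so boundary voxels only compete with real neighbours
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- v
  is_peak <- v >= thr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1L)) + dx, (2:(d[2] + 1L)) + dy,
              (2:(d[3] + 1L)) + dz]
    is_peak <- is_peak & (v > nb)
  }

  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(as_peak_table(data.frame(
      subject = character(), condition = character(), band = character(),
      x = numeric(), y = numeric(), z = numeric(), power = numeric())))
  }
  mm <- voxel_to_mm(idx - 1L, volume$affine)
  as_peak_table(data.frame(
    subject = subject, condition = condition, band = band,
    x = mm[, 1], y = mm[, 2], z = mm[, 3],
    power = v[idx]))
}

#' Pool peaks across conditions and bands for one subject
#'
#' Concatenates per-condition, per-band peak tables into the subject's
#' merged peak cloud. Nothing is deduplicated: repeated detections of
#' the same location across conditions are exactly what makes an active
#' area spatially dense, and the downstream density analysis relies on
#' them.
#'
#' @param peak_tables A list of peak tables, all from the same subject.
#' @return A single `"peak_table"` whose row count is the sum of the
#'   input row counts.
#' @export
merge_peaks <- function(peak_tables) {
  stopifnot(is.list(peak_tables), length(peak_tables) > 0)
  tabs <- lapply(peak_tables, as_peak_table)
  subjects <- unique(unlist(lapply(tabs, function(t) unique(t$subject))))
  if (length(subjects) > 1L)
    stop("merge_peaks pools peaks within one subject; got subjects: ",
         paste(subjects, collapse = ", "), call. = FALSE)
  as_peak_table(do.call(rbind, lapply(tabs, as.data.frame)))
}

#' Register peak coordinates through an affine transform
#'
#' Applies a 4x4 affine (e.g. subject-native to Talairach) to every peak
#' location; labels and power values are untouched.
#'
#' @param peaks A peak table.
#' @param affine 4x4 invertible matrix acting on homogeneous mm
#'   coordinates.
#' @return The peak table with transformed coordinates.
#' @export
to_talairach <- function(peaks, affine) {
  peaks <- as_peak_table(peaks)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("singular affine transform", call. = FALSE)
  if (nrow(peaks) == 0L) return(peaks)
  mm <- voxel_to_mm(peak_coords(peaks), affine)
  peaks$x <- mm[, 1]; peaks$y <- mm[, 2]; peaks$z <- mm[, 3]
  peaks
}
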