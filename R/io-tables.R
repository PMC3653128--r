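# Tab-separated table I/O: peak tables, reference coordinate tables and
# region reports. All coordinates are Talairach millimetres (x > 0 right,
# y > 0 anterior, z > 0 superior) and pass through unmodified.

PEAK_COLS <- c("subject", "condition", "band", "x", "y", "z", "power")
REF_COLS <- c("region", "hemisphere", "x", "y", "z", "source")

# published coordinate tables use the Unicode minus sign
.ascii_minus <- function(x) gsub("−", "-", x)

.numeric_col <- function(x, col) {
  v <- suppressWarnings(as.numeric(.ascii_minus(as.character(x))))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                 col, bad[1], as.character(x)[bad[1]]), call. = FALSE)
  if (anyNA(v))
    stop(sprintf("missing value in column '%s' at data row %d",
                 col, which(is.na(v))[1]), call. = FALSE)
  v
}

.check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Validate a peak table
#'
#' A peak table holds activation peaks: thresholded local maxima of
#' beamformer pseudo-Z power, one row per peak, with the subject,
#' condition and frequency band it was extracted from and its Talairach
#' location in mm.
#'
#' @param peaks A data.frame with columns `subject`, `condition`,
#'   `band`, `x`, `y`, `z`, `power`.
#' @return The validated data.frame (invisibly classed as
#'   `"peak_table"`), with coordinates numeric and band checked against
#'   [band_levels()].
#' @export
as_peak_table <- function(peaks) {
  .check_cols(peaks, PEAK_COLS, "peak table")
  peaks <- as.data.frame(peaks)[PEAK_COLS]
  peaks$subject <- as.character(peaks$subject)
  peaks$condition <- as.character(peaks$condition)
  peaks$band <- as.character(peaks$band)
  bad <- setdiff(unique(peaks$band), band_levels())
  if (length(bad))
    stop("unknown band value(s): ", paste(bad, collapse = ", "),
         "; allowed bands are: ", paste(band_levels(), collapse = ", "),
         call. = FALSE)
  for (col in c("x", "y", "z", "power"))
    peaks[[col]] <- .numeric_col(peaks[[col]], col)
  if (any(!is.finite(as.matrix(peaks[c("x", "y", "z")]))))
    stop("peak coordinates must be finite", call. = FALSE)
  if (any(peaks$power < 0))
    stop("pseudo-Z power must be >= 0", call. = FALSE)
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' Read a peak table from TSV
#'
#' @param path Path to a tab-separated file with a header row naming
#'   the columns `subject`, `condition`, `band`, `x`, `y`, `z`, `power`.
#' @return A validated `"peak_table"` data.frame, row order preserved.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = character())
  as_peak_table(df)
}

#' Write a peak table to TSV
#'
#' @param peaks A peak table (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- as_peak_table(peaks)
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Coordinates of peaks as a matrix
#'
#' @param peaks A peak table.
#' @return Numeric n x 3 matrix of Talairach mm coordinates.
#' @export
peak_coords <- function(peaks) {
  as.matrix(as_peak_table(peaks)[c("x", "y", "z")])
}

#' Read a reference coordinate table from TSV
#'
#' Reference tables carry literature locations of functional regions
#' (one row per region and hemisphere) against which group localizations
#' are compared.
#'
#' @param path Path to a tab-separated file with columns `region`,
#'   `hemisphere`, `x`, `y`, `z`, `source`.
#' @return A data.frame of class `"reference_table"`. Duplicate
#'   region/hemisphere pairs are an error.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path))
    stop("reference table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = character())
  as_reference_table(df)
}

#' Validate a reference coordinate table
#'
#' @param df A data.frame with columns `region`, `hemisphere`, `x`,
#'   `y`, `z`, `source`.
#' @return The validated data.frame, classed `"reference_table"`.
#' @export
as_reference_table <- function(df) {
  .check_cols(df, REF_COLS, "reference table")
  df <- as.data.frame(df)[REF_COLS]
  df$region <- as.character(df$region)
  df$hemisphere <- as.character(df$hemisphere)
  bad <- setdiff(unique(df$hemisphere), c("left", "right"))
  if (length(bad) && nrow(df))
    stop("hemisphere must be 'left' or 'right'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", "z")) df[[col]] <- .numeric_col(df[[col]], col)
  key <- paste(df$region, df$hemisphere)
  if (anyDuplicated(key))
    stop("duplicate region/hemisphere pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Write a reference coordinate table to TSV
#'
#' @param ref A reference table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(ref, path) {
  ref <- as_reference_table(ref)
  utils::write.table(ref, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

REPORT_COLS <- c("region", "hemisphere", "n_subjects", "mean_x", "mean_y",
                 "mean_z", "sd_x", "sd_y", "sd_z", "pooled_sd_mm",
                 "active", "distance_to_reference_mm")

#' Write a region report to TSV
#'
#' A region report has one row per reference region with the
#' cross-subject mean location, per-axis standard deviations, the pooled
#' standard deviation of peak-to-centroid distances, the activity flag
#' and the distance to the literature coordinate.
#'
#' @param report A data.frame as returned by [region_report_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(report, path) {
  .check_cols(report, REPORT_COLS, "region report")
  out <- as.data.frame(report)[REPORT_COLS]
  num <- c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z",
           "pooled_sd_mm", "distance_to_reference_mm")
  for (col in num) out[[col]] <- round(as.numeric(out[[col]]), 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a region report from TSV
#'
#' @param path Path to a report written by [write_region_report()].
#' @return A data.frame with the report columns typed.
#' @export
read_region_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  .check_cols(df, REPORT_COLS, "region report")
  df$active <- as.logical(df$active)
  df
}

#' Bundled literature reference coordinates
#'
#' Talairach coordinates of thirteen reaching/pointing-related cortical
#' regions (STS, PMV, IPL, VIP, FEF, SPL, mIPS, M1, S1, AG, SMA, SPOC,
#' PMd) as reported by fMRI meta-analyses, shipped with the package as a
#' reference table for cross-subject comparison.
#'
#' @return A `"reference_table"` data.frame with 13 rows.
#' @export
literature_regions <- function() {
  read_reference_table(system.file("extdata", "literature_regions.tsv",
                                   package = "apward", mustWork = TRUE))
}

#' Bundled group MEG localizations
#'
#' Mean Talairach locations and per-axis standard deviations of the
#' regions found consistently active across ten subjects in a
#' memory-guided reaching MEG study, for both hemispheres. Used together
#' with [literature_regions()] to recompute distances between MEG group
#' means and literature coordinates.
#'
#' @return A data.frame with columns `region`, `hemisphere`, `mean_x`,
#'   `mean_y`, `mean_z`, `sd_x`, `sd_y`, `sd_z`.
#' @export
meg_group_regions <- function() {
  path <- system.file("extdata", "meg_group_regions.tsv",
                      package = "apward", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  for (col in c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z"))
    df[[col]] <- .numeric_col(df[[col]], col)
  df
}
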