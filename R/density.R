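# Mesh analysis: normalised spatial density of activation peaks on a
# cubic millimetre mesh, used to gate which clusters receive finer
# Ward refinement.

#' Normalised spatial peak density on a cubic mesh
#'
#' Discretises space into axis-aligned cubes of edge `cube_mm`
#' (half-open, `[i*cube, (i+1)*cube)` per axis, anchored at `origin`),
#' counts the peaks falling in each cube and normalises counts by the
#' largest count. The densest cube therefore has density exactly 1, and
#' empty cubes are simply absent.
#'
#' @param peaks A peak table or n x 3 coordinate matrix (n >= 1).
#' @param cube_mm Cube edge length in mm (> 0; default 1).
#' @param origin Mesh origin in mm (default the Talairach origin
#'   `c(0, 0, 0)`).
#' @return A data.frame of class `"density_field"` with columns `ix`,
#'   `iy`, `iz` (integer cube indices), `count` and `density`;
#'   attributes `cube_mm`, `origin` and `max_count`.
#' @export
mesh_density <- function(peaks, cube_mm = 1, origin = c(0, 0, 0)) {
  pts <- if (inherits(peaks, "peak_table")) peak_coords(peaks) else as.matrix(peaks)
  if (nrow(pts) < 1L) stop("mesh_density needs at least one peak", call. = FALSE)
  if (!is.numeric(cube_mm) || cube_mm <= 0)
    stop("cube_mm must be > 0", call. = FALSE)
  idx <- .cube_index(pts, cube_mm, origin)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  counts <- table(key)
  first <- match(names(counts), key)
  field <- data.frame(
    ix = idx[first, 1], iy = idx[first, 2], iz = idx[first, 3],
    count = as.integer(counts),
    density = as.integer(counts) / max(counts)
  )
  field <- field[order(field$ix, field$iy, field$iz), , drop = FALSE]
  rownames(field) <- NULL
  structure(field, cube_mm = cube_mm, origin = origin,
            max_count = max(counts),
            class = c("density_field", "data.frame"))
}

.cube_index <- function(pts, cube_mm, origin) {
  idx <- floor(sweep(pts, 2, origin) / cube_mm)
  storage.mode(idx) <- "integer"
  idx
}

#' Density score of a cluster under a mesh field
#'
#' A cluster inherits its density from the mesh cubes its member peaks
#' occupy: the maximum (default) or the mean of those cubes' normalised
#' densities. The maximum is used for gating so that any cluster
#' containing a densely and repeatably activated spot qualifies for
#' finer refinement.
#'
#' @param points n x 3 matrix of the cluster's member locations, in the
#'   same coordinates the field was computed from.
#' @param field A `"density_field"` from [mesh_density()] computed over
#'   the same subject's merged peaks.
#' @param stat `"max"` (default) or `"mean"`.
#' @return A fraction in `[0, 1]`.
#' @export
cluster_density <- function(points, field, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(field, "density_field"))
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("empty cluster", call. = FALSE)
  idx <- .cube_index(points, attr(field, "cube_mm"), attr(field, "origin"))
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  fkey <- paste(field$ix, field$iy, field$iz, sep = ",")
  dens <- field$density[match(unique(key), fkey)]
  dens[is.na(dens)] <- 0   # members outside the field's support
  if (stat == "max") max(dens) else mean(dens)
}
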