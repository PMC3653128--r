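#' Frequency bands recognised by the pipeline
#'
#' Band labels for the four frequency ranges used when thresholding
#' beamformer power images: alpha (7-15 Hz), beta (15-35 Hz), low gamma
#' (35-55 Hz) and high gamma (55-120 Hz).
#'
#' @return Character vector of the four band labels.
#' @export
band_levels <- function() c("alpha", "beta", "low_gamma", "high_gamma")

#' Default per-band pseudo-Z power cutoffs
#'
#' Lower frequency bands carry systematically more power, so a single
#' threshold would bias peak extraction toward them. These
#' frequency-dependent cutoffs (alpha 2, beta 1.5, low gamma 1, high
#' gamma 0.5 pseudo-Z) equalise the chance of a voxel surviving
#' thresholding across bands.
#'
#' @return Named numeric vector, one cutoff per band.
#' @export
default_band_thresholds <- function() {
  c(alpha = 2, beta = 1.5, low_gamma = 1, high_gamma = 0.5)
}

#' Pipeline configuration
#'
#' Collects every tunable of the adaptive clustering pipeline with its
#' default. All lengths are in millimetres; thresholds are in pseudo-Z
#' units.
#'
#' @param band_thresholds Named numeric vector of per-band pseudo-Z
#'   cutoffs; see [default_band_thresholds()].
#' @param density_gate Normalised spatial density above which an
#'   Affinity Propagation cluster is refined by Ward clustering
#'   (fraction in `[0, 1]`, default 0.20).
#' @param radius_max_mm Target cluster radius for dendrogram cuts and
#'   for the cross-subject activity criterion (default 10 mm).
#' @param damping Affinity Propagation damping factor lambda in (0, 1)
#'   (default 0.5).
#' @param convergence_tol Relative message-change tolerance that stops
#'   Affinity Propagation (default 0.01, i.e. 1 percent).
#' @param mesh_cube_mm Edge length of the density mesh cubes
#'   (default 1 mm).
#' @param metric Similarity metric for Affinity Propagation:
#'   `"sqeuclidean"` (negative squared Euclidean distance, default) or
#'   `"euclidean"`.
#' @param density_stat How a cluster inherits a density from the mesh:
#'   maximum (default) or mean over the cubes occupied by its members.
#' @param match_radius_mm Maximum distance at which a subject's cluster
#'   may be matched to a reference coordinate (default 20 mm).
#' @param max_iter Iteration cap for Affinity Propagation (default 1000).
#' @param rng_seed Integer seed from which all simulation randomness
#'   derives.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(band_thresholds = default_band_thresholds(),
                            density_gate = 0.20,
                            radius_max_mm = 10,
                            damping = 0.5,
                            convergence_tol = 0.01,
                            mesh_cube_mm = 1,
                            metric = c("sqeuclidean", "euclidean"),
                            density_stat = c("max", "mean"),
                            match_radius_mm = 20,
                            max_iter = 1000L,
                            rng_seed = 1L) {
  metric <- match.arg(metric)
  density_stat <- match.arg(density_stat)
  bt <- unlist(band_thresholds)
  if (is.null(names(bt)) || !all(names(bt) %in% band_levels()))
    stop("band_thresholds must be named with bands among: ",
         paste(band_levels(), collapse = ", "), call. = FALSE)
  if (any(!is.finite(bt)) || any(bt < 0))
    stop("band thresholds must be finite and >= 0", call. = FALSE)
  if (!is.numeric(density_gate) || density_gate < 0 || density_gate > 1)
    stop("density_gate must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(radius_max_mm) || radius_max_mm <= 0)
    stop("radius_max_mm must be > 0", call. = FALSE)
  if (!is.numeric(damping) || damping <= 0 || damping >= 1)
    stop("damping must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(convergence_tol) || convergence_tol <= 0)
    stop("convergence_tol must be > 0", call. = FALSE)
  if (!is.numeric(mesh_cube_mm) || mesh_cube_mm <= 0)
    stop("mesh_cube_mm must be > 0", call. = FALSE)
  structure(list(
    band_thresholds = bt,
    density_gate = density_gate,
    radius_max_mm = radius_max_mm,
    damping = damping,
    convergence_tol = convergence_tol,
    mesh_cube_mm = mesh_cube_mm,
    metric = metric,
    density_stat = density_stat,
    match_radius_mm = match_radius_mm,
    max_iter = as.integer(max_iter),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file whose keys are a subset of the
#'   arguments of [pipeline_config()].
#' @return A validated `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$band_thresholds))
    raw$band_thresholds <- unlist(raw$band_thresholds)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Adaptive clustering pipeline configuration\n")
  cat("  band thresholds (pseudo-Z):",
      paste(sprintf("%s=%g", names(x$band_thresholds), x$band_thresholds),
            collapse = ", "), "\n")
  cat(sprintf("  density gate: %g   radius cap: %g mm   mesh cube: %g mm\n",
              x$density_gate, x$radius_max_mm, x$mesh_cube_mm))
  cat(sprintf("  AP: metric=%s damping=%g tol=%g max_iter=%d\n",
              x$metric, x$damping, x$convergence_tol, x$max_iter))
  invisible(x)
}
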