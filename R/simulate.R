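# Synthetic multi-subject peak clouds and pseudo-Z volumes with planted
# region structure. Emulates the statistical structure the pipeline
# assumes — dense, repeatable peaks scattered around active areas across
# conditions and bands, on top of sparse uniform background peaks — so
# the whole method is testable without MEG recordings.

#' Define a simulation
#'
#' @param regions Data.frame with one planted region per row: columns
#'   `label`, `hemisphere`, `x`, `y`, `z` (Talairach mm centre),
#'   `spread_mm` (per-axis Gaussian scatter of peaks) and
#'   `peaks_per_condition` (peaks drawn per condition x band).
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param subject_jitter_mm Per-axis SD of the Gaussian displacement of
#'   each region centre for each subject (anatomical variability).
#' @param conditions Character vector of condition ids; the default 12
#'   mirror a 2 hands x 3 wrist postures x 2 pro/anti pointing design.
#' @param bands Frequency bands simulated (default all four).
#' @param background_rate Uniform background peaks drawn per condition
#'   over the bounding box (>= 0).
#' @param bounding_box 2 x 3 matrix (rows: min, max) of the mm extents
#'   peaks and volumes are generated in.
#' @param noise_sd Additive white-noise SD for simulated volumes
#'   (pseudo-Z; default 0.1).
#' @param rng_seed Integer master seed; every output is a deterministic
#'   function of (`rng_seed`, subject index).
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(regions,
                            n_subjects = 10L,
                            subject_jitter_mm = 3,
                            conditions = default_conditions(),
                            bands = band_levels(),
                            background_rate = 10L,
                            bounding_box = talairach_bounding_box(),
                            noise_sd = 0.1,
                            rng_seed = 1L) {
  regions <- as.data.frame(regions)
  .check_cols(regions, c("label", "x", "y", "z", "spread_mm",
                         "peaks_per_condition"), "regions table")
  if (nrow(regions) == 0L && background_rate == 0)
    stop("simulation needs at least one region or background peaks",
         call. = FALSE)
  if (nrow(regions) && any(regions$spread_mm <= 0))
    stop("spread_mm must be > 0", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  bounding_box <- as.matrix(bounding_box)
  stopifnot(all(dim(bounding_box) == c(2L, 3L)),
            all(bounding_box[2, ] > bounding_box[1, ]))
  structure(list(regions = regions, n_subjects = as.integer(n_subjects),
                 subject_jitter_mm = subject_jitter_mm,
                 conditions = as.character(conditions),
                 bands = as.character(bands),
                 background_rate = as.integer(background_rate),
                 bounding_box = bounding_box, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

#' Default condition labels
#'
#' Twelve conditions crossing hand (left/right), wrist posture (three)
#' and pro-/anti-pointing.
#' @return Character vector of 12 condition ids.
#' @export
default_conditions <- function() {
  apply(expand.grid(hand = c("lh", "rh"), posture = c("p1", "p2", "p3"),
                    task = c("pro", "anti")), 1, paste, collapse = "_")
}

#' Approximate Talairach bounding box of the brain
#'
#' @return 2 x 3 matrix (rows min/max; columns x, y, z) in mm.
#' @export
talairach_bounding_box <- function() {
  rbind(min = c(-70, -105, -45), max = c(70, 75, 80))
}

#' Default simulation: planted regions at literature coordinates
#'
#' Plants the 13 bundled literature regions ([literature_regions()])
#' with 4 mm per-axis scatter and 2 peaks per condition x band (96 peaks
#' per region per subject across 12 conditions and 4 bands — the same
#' order of magnitude as real per-cluster peak counts), 3 mm per-axis
#' subject jitter, and 10 uniform background peaks per condition
#' (roughly 9 percent of all peaks).
#'
#' @param rng_seed Master seed.
#' @param spread_mm,peaks_per_condition,subject_jitter_mm,background_rate
#'   Overrides for the planted-structure parameters.
#' @return A `"simulation_spec"`.
#' @export
default_simulation_spec <- function(rng_seed = 1L, spread_mm = 4,
                                    peaks_per_condition = 2L,
                                    subject_jitter_mm = 3,
                                    background_rate = 10L) {
  ref <- literature_regions()
  regions <- data.frame(label = ref$region, hemisphere = ref$hemisphere,
                        x = ref$x, y = ref$y, z = ref$z,
                        spread_mm = spread_mm,
                        peaks_per_condition = as.integer(peaks_per_condition))
  simulation_spec(regions, subject_jitter_mm = subject_jitter_mm,
                  background_rate = background_rate, rng_seed = rng_seed)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
.sim_seed <- function(base, ...) {
  v <- as.numeric(c(...))
  mix <- (as.numeric(base) + sum(v * c(100003, 10007, 1009, 101)[seq_along(v)])) %%
    2147483629
  as.integer(mix)
}

# run expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Subject-specific planted region centres
#'
#' Each subject's region centres are the nominal centres displaced by an
#' isotropic Gaussian jitter (`subject_jitter_mm` per axis), emulating
#' anatomical variability. Deterministic given (`rng_seed`, subject).
#'
#' @param spec A `"simulation_spec"`.
#' @param subject_index Subject number (1-based).
#' @return n_regions x 3 matrix of mm centres.
#' @export
subject_region_centers <- function(spec, subject_index) {
  stopifnot(inherits(spec, "simulation_spec"))
  centers <- as.matrix(spec$regions[c("x", "y", "z")])
  if (nrow(centers) == 0L) return(centers)
  .with_seed(.sim_seed(spec$rng_seed, subject_index, 1), {
    centers + matrix(stats::rnorm(length(centers),
                                  sd = spec$subject_jitter_mm),
                     ncol = 3)
  })
}

#' Simulate one subject's merged peak table
#'
#' For every region and every condition x band cell,
#' `peaks_per_condition` peaks are drawn isotropic-Gaussian
#' (`spread_mm` per axis) around the subject-specific region centre,
#' with pseudo-Z values uniform in [band threshold, band threshold + 2].
#' Background peaks (uniform over the bounding box, random band) are
#' added per condition. Deterministic given (`rng_seed`,
#' `subject_index`).
#'
#' @param spec A `"simulation_spec"`.
#' @param subject_index Subject number (1-based).
#' @param thresholds Per-band pseudo-Z cutoffs used as the floor of
#'   simulated peak powers.
#' @return A `"peak_table"` with subject id `sprintf("sim%02d",
#'   subject_index)`.
#' @export
simulate_subject_peaks <- function(spec, subject_index,
                                   thresholds = default_band_thresholds()) {
  stopifnot(inherits(spec, "simulation_spec"))
  centers <- subject_region_centers(spec, subject_index)
  sid <- sprintf("sim%02d", subject_index)
  .with_seed(.sim_seed(spec$rng_seed, subject_index, 2), {
    out <- list()
    for (ri in seq_len(nrow(spec$regions))) {
      ppc <- spec$regions$peaks_per_condition[ri]
      spread <- spec$regions$spread_mm[ri]
      for (cond in spec$conditions) for (band in spec$bands) {
        pts <- matrix(stats::rnorm(3L * ppc, sd = spread), ncol = 3,
                      byrow = TRUE)
        pts <- sweep(pts, 2, centers[ri, ], `+`)
        thr <- thresholds[[band]]
        out[[length(out) + 1L]] <- data.frame(
          subject = sid, condition = cond, band = band,
          x = pts[, 1], y = pts[, 2], z = pts[, 3],
          power = stats::runif(ppc, thr, thr + 2))
      }
    }
    if (spec$background_rate > 0L) {
      bb <- spec$bounding_box
      for (cond in spec$conditions) {
        nb <- spec$background_rate
        pts <- sapply(1:3, function(a)
          stats::runif(nb, bb[1, a], bb[2, a]))
        pts <- matrix(pts, ncol = 3)
        band <- sample(spec$bands, nb, replace = TRUE)
        thr <- unname(unlist(thresholds)[band])
        out[[length(out) + 1L]] <- data.frame(
          subject = sid, condition = cond, band = band,
          x = pts[, 1], y = pts[, 2], z = pts[, 3],
          power = stats::runif(nb, thr, thr + 2))
      }
    }
    if (!length(out))
      stop("simulation produced no peaks", call. = FALSE)
    as_peak_table(do.call(rbind, out))
  })
}

#' Simulate a pseudo-Z power volume for one subject/band/condition
#'
#' Builds a 3 mm-voxel volume spanning the bounding box: a sum of
#' isotropic Gaussian bumps (height = band threshold + 1, width =
#' `spread_mm`) at the subject-specific region centres, plus seeded
#' white noise of SD `spec$noise_sd`. The affine maps voxel indices to
#' Talairach mm.
#'
#' @param spec A `"simulation_spec"`.
#' @param subject_index Subject number (1-based).
#' @param band Frequency band (sets bump height via its threshold).
#' @param condition Condition id (varies the noise realisation only).
#' @param voxel_mm Voxel edge length (default 3 mm).
#' @param thresholds Per-band pseudo-Z cutoffs.
#' @return A [power_volume()].
#' @export
simulate_volume <- function(spec, subject_index, band = "alpha",
                            condition = spec$conditions[1], voxel_mm = 3,
                            thresholds = default_band_thresholds()) {
  stopifnot(inherits(spec, "simulation_spec"))
  bb <- spec$bounding_box
  dims <- floor((bb[2, ] - bb[1, ]) / voxel_mm) + 1L
  if (any(dims < 1L))
    stop("bounding box smaller than one voxel", call. = FALSE)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- bb[1, ]
  centers <- subject_region_centers(spec, subject_index)
  ax <- lapply(1:3, function(a) bb[1, a] + voxel_mm * (seq_len(dims[a]) - 1L))
  v <- array(0, dims)
  height <- thresholds[[band]] + 1
  for (ri in seq_len(nrow(centers))) {
    w <- spec$regions$spread_mm[ri]
    gx <- exp(-(ax[[1]] - centers[ri, 1])^2 / (2 * w^2))
    gy <- exp(-(ax[[2]] - centers[ri, 2])^2 / (2 * w^2))
    gz <- exp(-(ax[[3]] - centers[ri, 3])^2 / (2 * w^2))
    v <- v + height * (gx %o% gy %o% gz)
  }
  if (spec$noise_sd > 0) {
    ci <- match(condition, spec$conditions)
    bi <- match(band, band_levels())
    v <- v + .with_seed(.sim_seed(spec$rng_seed, subject_index, 3,
                                  ci * 8 + bi), {
      array(stats::rnorm(prod(dims), sd = spec$noise_sd), dims)
    })
  }
  power_volume(v, affine)
}
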