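# The adaptive clustering pipeline: Affinity Propagation over a
# subject's merged peak cloud, mesh-density gating, Ward refinement of
# dense clusters to a target radius, and cross-subject consistency
# assessment against literature reference coordinates.

#' Run the adaptive clustering pipeline for one subject
#'
#' Stages: (1) Affinity Propagation partitions the subject's merged
#' peaks into exemplar-based clusters; (2) mesh analysis assigns every
#' cluster a normalised spatial density; (3) each AP cluster denser than
#' `config$density_gate` (and with at least 2 members) is replaced by
#' the sub-clusters obtained from a Ward dendrogram cut so that every
#' sub-cluster has radius at most `config$radius_max_mm`; sparser
#' clusters pass through unrefined. Refined sub-clusters with a single
#' member are flagged as non-active candidates.
#'
#' @param peaks Peak table for one subject, already merged across
#'   conditions and bands (>= 2 peaks).
#' @param config A [pipeline_config()].
#' @param verbose Emit stage-boundary messages with counts.
#' @return A list of class `"subject_result"`: `subject_id`, `ap`
#'   (the AP `"cluster_set"`), `density` (the `"density_field"`),
#'   `refined` (data.frame of final clusters: `cluster`, `parent_ap`,
#'   `refined`, `size`, `x`, `y`, `z`, `radius_mm`, `sd_dist_mm`,
#'   `density`, `active_candidate`), and `refined_members` (list of
#'   peak-row indices per refined cluster).
#' @export
run_subject <- function(peaks, config = pipeline_config(), verbose = FALSE) {
  peaks <- as_peak_table(peaks)
  if (nrow(peaks) < 2L)
    stop("run_subject needs at least 2 peaks", call. = FALSE)
  subject_id <- unique(peaks$subject)
  if (length(subject_id) > 1L)
    stop("peaks span multiple subjects: ",
         paste(subject_id, collapse = ", "), call. = FALSE)
  pts <- peak_coords(peaks)
  say <- function(...) if (verbose) message(sprintf(...))
  say("[%s] %d peaks", subject_id, nrow(pts))

  ap <- ap_cluster_peaks(pts, config)
  say("[%s] affinity propagation: %d clusters (%d iterations%s)",
      subject_id, nrow(ap$clusters), attr(ap, "ap")$iterations,
      if (attr(ap, "ap")$converged) "" else ", not converged")

  field <- mesh_density(pts, cube_mm = config$mesh_cube_mm)

  refined <- list()
  members <- list()
  n_gated <- 0L
  for (ci in seq_len(nrow(ap$clusters))) {
    m <- ap$members[[ci]]
    dens <- cluster_density(pts[m, , drop = FALSE], field,
                            stat = config$density_stat)
    gate <- dens > config$density_gate && length(m) >= 2L
    if (gate) {
      n_gated <- n_gated + 1L
      tree <- ward_linkage(pts[m, , drop = FALSE])
      sub <- cut_to_radius(tree, pts[m, , drop = FALSE],
                           config$radius_max_mm)
      for (si in seq_len(nrow(sub$clusters))) {
        row <- sub$clusters[si, ]
        members[[length(members) + 1L]] <- m[sub$members[[si]]]
        refined[[length(refined) + 1L]] <- data.frame(
          parent_ap = ci, refined = TRUE, size = row$size,
          x = row$x, y = row$y, z = row$z,
          radius_mm = row$radius_mm, sd_dist_mm = row$sd_dist_mm,
          density = dens)
      }
    } else {
      row <- ap$clusters[ci, ]
      members[[length(members) + 1L]] <- m
      refined[[length(refined) + 1L]] <- data.frame(
        parent_ap = ci, refined = FALSE, size = row$size,
        x = row$x, y = row$y, z = row$z,
        radius_mm = row$radius_mm, sd_dist_mm = row$sd_dist_mm,
        density = dens)
    }
  }
  refined <- do.call(rbind, refined)
  refined <- cbind(cluster = seq_len(nrow(refined)), refined)
  refined$active_candidate <- refined$size > 1L
  say("[%s] density gate (> %g): %d of %d clusters refined -> %d final clusters",
      subject_id, config$density_gate, n_gated, nrow(ap$clusters),
      nrow(refined))

  structure(list(subject_id = subject_id, ap = ap, density = field,
                 refined = refined, refined_members = members,
                 points = pts, config = config),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("subject %s: %d peaks, %d AP clusters, %d refined clusters\n",
              x$subject_id, nrow(x$points), nrow(x$ap$clusters),
              nrow(x$refined)))
  invisible(x)
}

#' Euclidean distance between a group mean and a reference coordinate
#'
#' @param group_mean,reference Length-3 mm coordinate vectors.
#' @return Distance in mm.
#' @export
distance_to_reference <- function(group_mean, reference) {
  group_mean <- as.numeric(group_mean); reference <- as.numeric(reference)
  stopifnot(length(group_mean) == 3L, length(reference) == 3L,
            all(is.finite(group_mean)), all(is.finite(reference)))
  sqrt(sum((group_mean - reference)^2))
}

#' Match refined clusters to reference regions across subjects
#'
#' For every reference region, each subject contributes the refined
#' cluster whose centroid is nearest to the reference coordinate,
#' provided it lies within `match_radius`; subjects with no such cluster
#' contribute nothing to that region. Single-peak clusters are flagged
#' non-active candidates by [run_subject()] and are never matched: a
#' lone stray detection cannot represent a consistently active region,
#' and letting it shadow a genuine multi-peak cluster nearby would veto
#' the region for the whole group. The group mean is the mean of the
#' matched centroids and the per-axis SDs use the n-1 denominator
#' (reported as 0 when only one subject matched).
#'
#' @param results List of `"subject_result"` objects.
#' @param reference A `"reference_table"`.
#' @param match_radius Matching radius in mm (default 20).
#' @return A list of `"region_report"` objects (activity still
#'   undecided); each holds the matched per-subject centroids, sizes
#'   and member-to-centroid distance vectors.
#' @export
match_regions <- function(results, reference, match_radius = 20) {
  stopifnot(length(results) >= 1L)
  reference <- as_reference_table(reference)
  if (nrow(reference) == 0L)
    stop("empty reference table", call. = FALSE)
  lapply(seq_len(nrow(reference)), function(ri) {
    ref <- reference[ri, ]
    refxyz <- as.numeric(ref[c("x", "y", "z")])
    matched <- list()
    for (res in results) {
      keep <- which(res$refined$active_candidate)
      if (!length(keep)) next
      cen <- as.matrix(res$refined[keep, c("x", "y", "z")])
      d <- sqrt(colSums((t(cen) - refxyz)^2))
      best <- keep[which.min(d)]
      if (length(best) && min(d) <= match_radius) {
        m <- res$refined_members[[best]]
        ctr <- as.numeric(res$refined[best, c("x", "y", "z")])
        dists <- sqrt(colSums((t(res$points[m, , drop = FALSE]) - ctr)^2))
        matched[[length(matched) + 1L]] <- list(
          subject_id = res$subject_id, centroid = ctr,
          size = res$refined$size[best], member_dists = dists,
          distance_to_reference = d[best])
      }
    }
    n <- length(matched)
    if (n) {
      cen <- do.call(rbind, lapply(matched, `[[`, "centroid"))
      gmean <- colMeans(cen)
      sds <- if (n > 1L) apply(cen, 2, stats::sd) else c(0, 0, 0)
    } else {
      gmean <- c(NA_real_, NA_real_, NA_real_); sds <- c(NA_real_, NA_real_, NA_real_)
    }
    structure(list(region = ref$region, hemisphere = ref$hemisphere,
                   reference = refxyz, matched = matched,
                   n_subjects = n, group_mean = gmean, axis_sd = sds,
                   pooled_sd_mm = NA_real_, per_subject_sd_mm = NULL,
                   active = NA,
                   distance_to_reference_mm = if (n)
                     distance_to_reference(gmean, refxyz) else NA_real_),
              class = "region_report")
  })
}

#' Decide whether a region is consistently active
#'
#' Pools, over all matched subjects, the distances of member peaks to
#' their own subject's cluster centroid. The region is called active
#' when the standard deviation of the pooled distances is below
#' `radius_max` (1 cm by default) and every matched cluster has more
#' than one peak. Per-subject SDs are also recorded, since the
#' consistency requirement can alternatively be read per subject; the
#' pooled SD is decisive.
#'
#' @param report A `"region_report"` from [match_regions()].
#' @param radius_max Activity SD bound in mm (default 10).
#' @return The report with `pooled_sd_mm`, `per_subject_sd_mm` and
#'   `active` filled in.
#' @export
decide_active <- function(report, radius_max = 10) {
  stopifnot(inherits(report, "region_report"))
  if (report$n_subjects == 0L) {
    report$active <- FALSE
    return(report)
  }
  pooled <- unlist(lapply(report$matched, `[[`, "member_dists"))
  report$pooled_sd_mm <- if (length(pooled) > 1L) stats::sd(pooled) else 0
  report$per_subject_sd_mm <- vapply(report$matched, function(m)
    if (length(m$member_dists) > 1L) stats::sd(m$member_dists) else 0,
    numeric(1))
  all_multi <- all(vapply(report$matched, `[[`, numeric(1), "size") > 1)
  report$active <- isTRUE(report$pooled_sd_mm < radius_max && all_multi)
  report
}

#' Flatten region reports to a table
#'
#' @param reports List of decided `"region_report"` objects.
#' @return A data.frame with one row per region, in the column layout
#'   of [write_region_report()].
#' @export
region_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    region = r$region, hemisphere = r$hemisphere,
    n_subjects = r$n_subjects,
    mean_x = r$group_mean[1], mean_y = r$group_mean[2],
    mean_z = r$group_mean[3],
    sd_x = r$axis_sd[1], sd_y = r$axis_sd[2], sd_z = r$axis_sd[3],
    pooled_sd_mm = r$pooled_sd_mm, active = r$active,
    distance_to_reference_mm = r$distance_to_reference_mm)))
}

#' Localize consistently active regions across subjects
#'
#' Convenience wrapper chaining [match_regions()] and [decide_active()]
#' over all reference regions.
#'
#' @param results List of `"subject_result"` objects from
#'   [run_subject()].
#' @param reference A `"reference_table"` (default the bundled
#'   [literature_regions()]).
#' @param config A [pipeline_config()] supplying `match_radius_mm` and
#'   `radius_max_mm`.
#' @return A list with `reports` (decided region reports) and `table`
#'   (their flat data.frame).
#' @export
localize_regions <- function(results, reference = literature_regions(),
                             config = pipeline_config()) {
  reports <- match_regions(results, reference,
                           match_radius = config$match_radius_mm)
  reports <- lapply(reports, decide_active,
                    radius_max = config$radius_max_mm)
  list(reports = reports, table = region_report_table(reports))
}
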