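# Affinity Propagation exemplar clustering of activation peaks.
#
# Message-passing clustering (Frey & Dueck's responsibility/availability
# scheme) with damped updates, median self-preferences and deterministic
# lowest-index tie-breaking. Chosen over k-means because the number of
# active regions is unknown a priori.

#' Build a peak similarity matrix
#'
#' Off-diagonal similarities are negative (squared) Euclidean distances
#' between peak locations; every diagonal entry (the shared exemplar
#' preference) is the median of the off-diagonal values, which gives all
#' peaks the same chance of becoming an exemplar while keeping the
#' preference on the scale of the data.
#'
#' @param points n x 3 matrix of peak locations in mm (a peak table is
#'   also accepted).
#' @param metric `"sqeuclidean"` (default) for s(i,k) = -||pi - pk||^2,
#'   or `"euclidean"` for s(i,k) = -||pi - pk||.
#' @return An n x n similarity matrix.
#' @export
build_similarity <- function(points, metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(points, "peak_table")) points <- peak_coords(points)
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point", call. = FALSE)
  if (any(!is.finite(points)))
    stop("non-finite coordinate in input points", call. = FALSE)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  S <- if (metric == "sqeuclidean") -(d^2) else -d
  diag(S) <- if (n == 1L) 0 else stats::median(S[row(S) != col(S)])
  dimnames(S) <- NULL
  S
}

#' Affinity Propagation clustering
#'
#' Iterates the standard responsibility/availability updates:
#' \deqn{r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}[a(i,k') + s(i,k')]}
#' \deqn{a(i,k) \leftarrow \min\{0,\; r(k,k) + \sum_{i' \notin \{i,k\}}
#'   \max(0, r(i',k))\},\quad i \ne k}
#' \deqn{a(k,k) \leftarrow \sum_{i' \ne k} \max(0, r(i',k))}
#' each message damped as `lambda * old + (1 - lambda) * new`.
#'
#' Three safeguards of the classic reference implementation are kept,
#' because the raw update rules are degenerate at their fixed points:
#' the exemplar criterion `r(k,k) + a(k,k)` approaches 0 to machine
#' precision for every point, so its sign — and hence the exemplar set —
#' would otherwise be decided by rounding error. (1) A tiny,
#' deterministic degeneracy-breaking perturbation (machine-epsilon
#' scale, seeded from the problem size) is added to the similarities;
#' (2) iteration stops only when the largest relative message change is
#' below `tol` *and* the exemplar set has been stable for `stable_iter`
#' consecutive iterations (or at `max_iter`, with a warning and
#' `converged = FALSE`); (3) after convergence each exemplar is refined
#' to the medoid of its cluster (the member maximising the sum of
#' within-cluster similarities). Exemplars are the indices with
#' `r(k,k) + a(k,k) > 0` (if none, the columns achieving the row maxima
#' of `r + a`); every point is then assigned to the exemplar with the
#' highest similarity, ties to the lowest index, exemplars to
#' themselves.
#'
#' @param S Similarity matrix from [build_similarity()].
#' @param damping Damping factor lambda in (0, 1); default 0.5.
#' @param tol Relative message-change stopping tolerance; default 0.01.
#' @param max_iter Iteration cap; default 1000.
#' @param stable_iter Number of consecutive iterations the exemplar set
#'   must be unchanged before stopping; default 50.
#' @param refine Apply the final medoid refinement of exemplars
#'   (default `TRUE`).
#' @return A list with `exemplars` (integer vector), `assignment`
#'   (length-n integer vector of exemplar indices), `iterations`,
#'   `converged` and `net_similarity`.
#' @export
affinity_propagation <- function(S, damping = 0.5, tol = 0.01,
                                 max_iter = 1000L, stable_iter = 50L,
                                 refine = TRUE) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n == 0L) stop("empty similarity matrix", call. = FALSE)
  if (damping <= 0 || damping >= 1)
    stop("damping must lie strictly between 0 and 1", call. = FALSE)
  if (n == 1L) {
    return(list(exemplars = 1L, assignment = 1L, iterations = 0L,
                converged = TRUE, net_similarity = S[1, 1]))
  }
  if (diff(range(S)) == 0) {
    # fully degenerate input (e.g. all points coincident): every exemplar
    # choice is equivalent; take the lowest index deterministically
    return(list(exemplars = 1L, assignment = rep(1L, n), iterations = 0L,
                converged = TRUE, net_similarity = S[1, 1]))
  }

  # deterministic eps-scale perturbation; breaks fixed-point degeneracy
  # without measurably moving the objective
  S <- S + .with_seed(n + 7L, {
    (.Machine$double.eps * S + .Machine$double.xmin * 100) *
      matrix(stats::rnorm(n * n), n, n)
  })

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  eps <- 1e-12
  ii <- seq_len(n)
  converged <- FALSE
  it <- 0L
  last_ex <- NULL
  stable <- 0L
  while (it < max_iter) {
    it <- it + 1L

    # responsibilities: r(i,k) = s(i,k) - max_{k'!=k} [a(i,k') + s(i,k')]
    AS <- A + S
    k1 <- max.col(AS, ties.method = "first")
    top <- cbind(ii, k1)
    m1 <- AS[top]
    AS[top] <- -Inf
    m2 <- AS[cbind(ii, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1                 # column-major recycling: row i minus m1[i]
    Rnew[top] <- S[top] - m2
    Rnew <- damping * R + (1 - damping) * Rnew

    # availabilities
    Rp <- pmax(Rnew, 0)
    diag(Rp) <- diag(Rnew)         # r(k,k) enters the column sum as-is
    cs <- colSums(Rp)              # r(k,k) + sum_{i'!=k} max(0, r(i',k))
    Anew <- pmin(rep(cs, each = n) - Rp, 0)
    diag(Anew) <- cs - diag(Rnew)  # a(k,k) = sum_{i'!=k} max(0, r(i',k))
    Anew <- damping * A + (1 - damping) * Anew

    delta <- max(abs(Rnew - R) / (abs(R) + eps),
                 abs(Anew - A) / (abs(A) + eps))
    R <- Rnew
    A <- Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (delta < tol && stable >= stable_iter) { converged <- TRUE; break }
  }
  if (!converged)
    warning("affinity propagation did not converge within ", max_iter,
            " iterations", call. = FALSE)

  exemplars <- which(diag(R) + diag(A) > 0)
  if (length(exemplars) == 0L)
    exemplars <- sort(unique(max.col(R + A, ties.method = "first")))

  if (refine && length(exemplars)) {
    cl <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
    cl[exemplars] <- seq_along(exemplars)
    for (k in seq_along(exemplars)) {
      m <- which(cl == k)
      exemplars[k] <- m[which.max(colSums(S[m, m, drop = FALSE]))]
    }
    exemplars <- sort(unique(exemplars))
  }

  # assign to the most similar exemplar, ties to the lowest index
  Sx <- S[, exemplars, drop = FALSE]
  assignment <- exemplars[max.col(Sx, ties.method = "first")]
  assignment[exemplars] <- exemplars

  net <- sum(S[cbind(ii[-exemplars], assignment[-exemplars])]) +
    sum(diag(S)[exemplars])
  list(exemplars = exemplars, assignment = assignment, iterations = it,
       converged = converged, net_similarity = net)
}

#' Net similarity of an exemplar set
#'
#' The Affinity Propagation objective: the sum over non-exemplars of
#' their similarity to their best exemplar, plus the exemplar
#' preferences.
#'
#' @param S Similarity matrix.
#' @param exemplars Integer vector of exemplar indices.
#' @return A scalar (larger is better).
#' @export
net_similarity <- function(S, exemplars) {
  S <- as.matrix(S)
  others <- setdiff(seq_len(nrow(S)), exemplars)
  best <- if (length(others))
    sum(apply(S[others, exemplars, drop = FALSE], 1, max)) else 0
  best + sum(diag(S)[exemplars])
}

#' Assemble a cluster set from points and an assignment
#'
#' A cluster set is a flat partition of peaks with per-cluster geometry:
#' centroid (member mean), radius (maximum member-to-centroid distance)
#' and the standard deviation of member-to-centroid distances used by
#' the activity criterion.
#'
#' @param points n x 3 matrix of peak locations in mm.
#' @param assignment Length-n vector of cluster labels (e.g. exemplar
#'   indices from [affinity_propagation()]).
#' @param exemplars Optional integer vector of exemplar point indices,
#'   aligned with the distinct labels.
#' @return A list of class `"cluster_set"` with `clusters` (data.frame:
#'   `cluster`, `exemplar`, `size`, `x`, `y`, `z`, `radius_mm`,
#'   `sd_dist_mm`), `members` (list of member index vectors) and
#'   `assignment`.
#' @export
cluster_set <- function(points, assignment, exemplars = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(length(assignment) == n, n >= 1L)
  labels <- sort(unique(assignment))
  members <- lapply(labels, function(l) which(assignment == l))
  geom <- lapply(members, function(m) .cluster_geometry(points[m, , drop = FALSE]))
  clusters <- data.frame(
    cluster = seq_along(labels),
    exemplar = if (is.null(exemplars)) NA_integer_ else as.integer(labels),
    size = vapply(members, length, integer(1)),
    x = vapply(geom, `[[`, numeric(1), "cx"),
    y = vapply(geom, `[[`, numeric(1), "cy"),
    z = vapply(geom, `[[`, numeric(1), "cz"),
    radius_mm = vapply(geom, `[[`, numeric(1), "radius"),
    sd_dist_mm = vapply(geom, `[[`, numeric(1), "sd_dist")
  )
  structure(list(clusters = clusters, members = members,
                 assignment = match(assignment, labels), points = points),
            class = "cluster_set")
}

.cluster_geometry <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(colSums((t(pts) - ctr)^2))
  list(cx = ctr[1], cy = ctr[2], cz = ctr[3],
       radius = max(d),
       sd_dist = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Cluster peaks by Affinity Propagation
#'
#' Convenience wrapper: builds the similarity matrix from a peak table
#' (or point matrix) and runs [affinity_propagation()] with the
#' configured damping and tolerance.
#'
#' @param peaks A peak table or n x 3 coordinate matrix.
#' @param config A [pipeline_config()].
#' @return A `"cluster_set"`; the AP diagnostics (`iterations`,
#'   `converged`, `net_similarity`, `exemplars`) are attached as
#'   attribute `"ap"`.
#' @export
ap_cluster_peaks <- function(peaks, config = pipeline_config()) {
  pts <- if (inherits(peaks, "peak_table")) peak_coords(peaks) else as.matrix(peaks)
  S <- build_similarity(pts, metric = config$metric)
  # oscillation guard: if message passing fails to settle at the
  # configured damping, retry with stronger damping (the standard remedy
  # for AP oscillation) before accepting a degenerate solution
  damping <- config$damping
  repeat {
    fit <- withCallingHandlers(
      affinity_propagation(S, damping = damping,
                           tol = config$convergence_tol,
                           max_iter = config$max_iter),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (fit$converged || damping >= 0.9) break
    damping <- min(0.9, damping + 0.2)
    message(sprintf(
      "affinity propagation oscillated; retrying with damping %.1f",
      damping))
  }
  if (!fit$converged)
    warning("affinity propagation did not converge, even with damping ",
            damping, call. = FALSE)
  cs <- cluster_set(pts, fit$assignment, exemplars = fit$exemplars)
  attr(cs, "ap") <- c(fit, list(damping_used = damping))
  cs
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d clusters over %d points\n",
              nrow(x$clusters), length(x$assignment)))
  cat(sprintf("  sizes: %s\n", paste(utils::head(sort(x$clusters$size,
              decreasing = TRUE), 10), collapse = ", ")))
  invisible(x)
}
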