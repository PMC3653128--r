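# Ward hierarchical clustering of a cluster's member peaks, with
# radius-constrained top-down dendrogram cuts.

#' Ward linkage dendrogram with ESS-increment heights
#'
#' Agglomerative clustering that, at each step, merges the pair of
#' clusters whose union minimally increases the total within-cluster
#' error sum of squares, ESS(c) = sum of squared member-to-centroid
#' distances. The recorded height of each merge is that increase,
#' \eqn{\Delta ESS = ESS(a \cup b) - ESS(a) - ESS(b)} in mm^2 —
#' guaranteed non-decreasing along the merge sequence, so the tree is
#' monotone. The merge structure is computed by
#' [stats::hclust()] with Ward (`"ward.D2"`) linkage, whose heights
#' equal \eqn{\sqrt{2\,\Delta ESS}}; they are converted here.
#'
#' @param points n x 3 matrix of member locations in mm (n >= 2).
#' @return An object of class `"ward_tree"`: list with `merge` (the
#'   [stats::hclust()] merge matrix), `height` (Delta-ESS per merge,
#'   mm^2), `order`, and `n`.
#' @export
ward_linkage <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("ward_linkage needs at least 2 points", call. = FALSE)
  if (any(!is.finite(points)))
    stop("non-finite coordinate in input points", call. = FALSE)
  hc <- stats::hclust(stats::dist(points), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height^2 / 2,
                 order = hc$order, n = nrow(points)),
            class = "ward_tree")
}

#' Convert a Ward tree to a standard hclust object
#'
#' Heights are exported on the conventional `"ward.D2"` scale
#' \eqn{\sqrt{2\,\Delta ESS}} so the tree can be plotted or cut with
#' standard dendrogram tooling.
#'
#' @param x A `"ward_tree"`.
#' @param ... Unused.
#' @return An object of class `"hclust"`.
#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = sqrt(2 * x$height),
                 order = x$order, labels = NULL, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# member leaf indices for every internal node of an hclust-style merge
.node_members <- function(merge) {
  m <- nrow(merge)
  members <- vector("list", m)
  for (i in seq_len(m)) {
    left <- merge[i, 1]; right <- merge[i, 2]
    members[[i]] <- c(if (left < 0) -left else members[[left]],
                      if (right < 0) -right else members[[right]])
  }
  members
}

#' Cut a Ward tree into sub-clusters within a target radius
#'
#' Descends from the root and emits a node as a flat cluster as soon as
#' the maximum distance of its member points from their centroid is at
#' most `radius_max`; otherwise its two children are examined. Leaves
#' have radius 0, so the recursion always terminates and the emitted
#' clusters partition the points. This is the deterministic replacement
#' for manual trial-and-error tree cutting: every emitted cluster
#' carries a hard radius guarantee.
#'
#' @param tree A `"ward_tree"` from [ward_linkage()].
#' @param points The n x 3 matrix the tree was built from.
#' @param radius_max Radius cap in mm (> 0; the pipeline default is
#'   10 mm, i.e. 1 cm).
#' @return A `"cluster_set"` over `points`.
#' @export
cut_to_radius <- function(tree, points, radius_max) {
  stopifnot(inherits(tree, "ward_tree"))
  points <- as.matrix(points)
  if (!is.numeric(radius_max) || radius_max <= 0)
    stop("radius_max must be > 0", call. = FALSE)
  if (nrow(points) != tree$n)
    stop("tree was built from ", tree$n, " points, got ", nrow(points),
         call. = FALSE)
  members <- .node_members(tree$merge)
  assignment <- integer(tree$n)
  next_label <- 0L
  stack <- list(nrow(tree$merge))        # root node
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- if (node < 0) -node else members[[node]]
    pts <- points[idx, , drop = FALSE]
    r <- max(sqrt(colSums((t(pts) - colMeans(pts))^2)))
    if (node < 0 || r <= radius_max) {
      next_label <- next_label + 1L
      assignment[idx] <- next_label
    } else {
      stack <- c(stack, tree$merge[node, 1], tree$merge[node, 2])
    }
  }
  cluster_set(points, assignment)
}
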