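# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package
# implementations they check.

# random peak table with valid fields
random_peak_table <- function(n, subject = "s1", seed = 1) {
  set.seed(seed)
  data.frame(
    subject = subject,
    condition = sample(sprintf("c%d", 1:3), n, replace = TRUE),
    band = sample(band_levels(), n, replace = TRUE),
    x = round(runif(n, -70, 70), 3),
    y = round(runif(n, -100, 70), 3),
    z = round(runif(n, -40, 75), 3),
    power = round(runif(n, 0, 5), 3)
  )
}

# a Gaussian blob of points around a centre
blob <- function(n, center, spread) {
  sweep(matrix(stats::rnorm(3 * n, sd = spread), ncol = 3), 2, center, `+`)
}

# a Gaussian blob truncated to a hard radius, so the lobe's own radius
# is bounded by construction (mirrors a compact activation focus)
truncated_blob <- function(n, center, spread, rmax) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    p <- matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
    p <- p[sqrt(rowSums(p^2)) <= rmax, , drop = FALSE]
    out <- rbind(out, p)
  }
  sweep(out[seq_len(n), , drop = FALSE], 2, center, `+`)
}

# exhaustive search over all nonempty exemplar subsets
oracle_best_netsim <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (m in 1:(2^n - 1)) {
    E <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    v <- net_similarity(S, E)
    if (v > best) best <- v
  }
  best
}

# per-voxel 26-neighbour scan, straight from the definition
oracle_local_maxima <- function(v, thr) {
  d <- dim(v)
  out <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (v[i, j, k] < thr) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      if (v[i, j, k] <= v[ii, jj, kk]) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, c(i, j, k))
  }
  out
}

# greedy Ward agglomeration recomputing delta-ESS for every pair at
# every step; returns merge heights and the partition after each merge
oracle_ward <- function(points) {
  ess <- function(m) {
    if (nrow(m) == 1L) return(0)
    sum(sweep(m, 2, colMeans(m))^2)
  }
  cl <- lapply(seq_len(nrow(points)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(cl) > 1L) {
    best <- NULL; bd <- Inf
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- ess(points[c(cl[[i]], cl[[j]]), , drop = FALSE]) -
        ess(points[cl[[i]], , drop = FALSE]) -
        ess(points[cl[[j]], , drop = FALSE])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    cl[[best[1]]] <- sort(c(cl[[best[1]]], cl[[best[2]]]))
    cl[[best[2]]] <- NULL
    partitions[[length(partitions) + 1L]] <-
      lapply(cl, sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition after each merge of a ward_tree, for comparison with the
# greedy oracle (encoding-independent)
ward_tree_partitions <- function(tree) {
  n <- tree$n
  cl <- lapply(seq_len(n), identity)
  labels <- seq_len(n)        # which current cluster holds each merge node
  node_of <- integer(2 * n)   # map hclust node -> position in cl
  out <- list()
  current <- lapply(seq_len(n), identity)
  id <- -(seq_len(n))
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
    ia <- match(a, id); ib <- match(b, id)
    current[[ia]] <- sort(c(current[[ia]], current[[ib]]))
    id[ia] <- i
    current <- current[-ib]; id <- id[-ib]
    out[[i]] <- lapply(current, sort)
  }
  out
}

# canonical form of a partition (list of sorted member vectors, sorted
# by first element) so two partitions compare with identical()
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}

# labels-as-integers partition from a cluster_set
partition_of <- function(cs) canonical_partition(cs$members)
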