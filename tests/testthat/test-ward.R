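test_that("two points merge at height d^2/2", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0))
  tree <- ward_linkage(pts)
  expect_equal(tree$height, 2.0)   # 2 * (d/2)^2
})

test_that("three collinear points merge nearest pair first", {
  pts <- cbind(c(0, 1, 10), 0, 0)
  tree <- ward_linkage(pts)
  expect_equal(tree$height[1], 0.5)
  # joining {0,1} (centroid 0.5, ESS 0.5) with {10}:
  # ESS(all) = sum((c(0,1,10)-11/3)^2) -> delta = ESS(all) - 0.5
  delta2 <- sum((c(0, 1, 10) - 11 / 3)^2) - 0.5
  expect_equal(tree$height[2], delta2)
})

test_that("merge sequences and heights match the exhaustive greedy oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:7, 1)
    pts <- matrix(runif(3 * n, 0, 30), ncol = 3)
    tree <- ward_linkage(pts)
    orc <- oracle_ward(pts)
    expect_equal(tree$height, orc$heights, tolerance = 1e-9)
    got <- ward_tree_partitions(tree)
    for (step in seq_along(orc$partitions)) {
      expect_identical(canonical_partition(got[[step]]),
                       canonical_partition(orc$partitions[[step]]))
    }
  }
})

test_that("dendrogram heights are monotone non-decreasing", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(3 * 40, sd = 10), ncol = 3)
    tree <- ward_linkage(pts)
    expect_true(all(diff(tree$height) >= -1e-9))
  }
})

test_that("ward trees export to hclust on the conventional scale", {
  set.seed(1)
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  tree <- ward_linkage(pts)
  hc <- as.hclust(tree)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, sqrt(2 * tree$height))
  expect_equal(hc$merge, tree$merge)
})

test_that("radius cuts respect the cap and partition the points", {
  # compact cloud: root already satisfies the cap
  set.seed(4)
  pts <- blob(30, c(10, 10, 10), 1.5)
  cs <- cut_to_radius(ward_linkage(pts), pts, 10)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$size, 30L)

  # randomized inputs: every emitted cluster within the cap, points conserved
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:60, 1)
    pts <- matrix(runif(3 * n, 0, 80), ncol = 3)
    rmax <- runif(1, 3, 25)
    cs <- cut_to_radius(ward_linkage(pts), pts, rmax)
    expect_true(all(cs$clusters$radius_mm <= rmax + 1e-9))
    expect_equal(sort(unlist(cs$members)), 1:n)
  }
})

test_that("a wide two-lobe composite splits into its two lobes", {
  # two compact ~8 mm lobes 30 mm apart: the composite has radius
  # ~17-22 mm, far over the cap, but each lobe fits within 11 mm
  set.seed(21)
  pts <- rbind(truncated_blob(20, c(0, 0, 0), 4, 8),
               truncated_blob(20, c(30, 0, 0), 4, 8))
  tree <- ward_linkage(pts)
  whole <- cluster_set(pts, rep(1L, 40))
  expect_gt(whole$clusters$radius_mm, 15)   # composite is too wide
  cs <- cut_to_radius(tree, pts, 11)
  expect_equal(nrow(cs$clusters), 2L)
  expect_identical(partition_of(cs),
                   canonical_partition(list(1:20, 21:40)))
  expect_true(all(cs$clusters$radius_mm <= 11))
})

test_that("degenerate radius caps give singleton clusters", {
  set.seed(2)
  pts <- matrix(runif(15, 0, 10), ncol = 3)
  tree <- ward_linkage(pts)
  cs <- cut_to_radius(tree, pts, 1e-12)
  expect_equal(nrow(cs$clusters), 5L)
  expect_true(all(cs$clusters$size == 1L))
  expect_error(cut_to_radius(tree, pts, 0), "radius_max")
})

test_that("tightening the radius cap never reduces the cluster count", {
  set.seed(9)
  pts <- matrix(runif(3 * 50, 0, 50), ncol = 3)
  tree <- ward_linkage(pts)
  counts <- vapply(c(40, 25, 15, 10, 6, 3, 1),
                   function(r) nrow(cut_to_radius(tree, pts, r)$clusters),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ward_linkage rejects degenerate input", {
  expect_error(ward_linkage(matrix(0, 1, 3)), "at least 2")
})
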