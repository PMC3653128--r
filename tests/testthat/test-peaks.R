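make_volume <- function(values, voxel = 3, origin = c(0, 0, 0)) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- origin
  power_volume(values, aff)
}

test_that("constant volumes have no strict local maxima", {
  vol <- make_volume(array(5, dim = c(6, 6, 6)))
  expect_equal(nrow(extract_local_maxima(vol, "alpha")), 0L)
})

test_that("a single bump above threshold yields one peak at its mm location", {
  v <- array(0, dim = c(9, 9, 9))
  ctr <- c(5, 5, 5)
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    v[i, j, k] <- 3 * exp(-sum((c(i, j, k) - ctr)^2) / 6)
  vol <- make_volume(v, voxel = 3, origin = c(-12, -12, -12))
  pk <- extract_local_maxima(vol, "alpha")
  expect_equal(nrow(pk), 1L)
  # voxel (5,5,5), 0-based (4,4,4), mm = -12 + 3*4 = 0
  expect_equal(unname(unlist(pk[c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(pk$power, 3)
})

test_that("band thresholds gate the same bump differently", {
  v <- array(0, dim = c(7, 7, 7))
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    v[i, j, k] <- 1.2 * exp(-sum((c(i, j, k) - 4)^2) / 4)
  vol <- make_volume(v)
  expect_equal(nrow(extract_local_maxima(vol, "alpha")), 0L)     # cutoff 2
  expect_equal(nrow(extract_local_maxima(vol, "low_gamma")), 1L) # cutoff 1
})

test_that("extraction matches the exhaustive neighbour-scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- array(rnorm(10 * 11 * 9), dim = c(10, 11, 9))
    vol <- make_volume(v)
    thr <- 0.5
    got <- extract_local_maxima(vol, "high_gamma",
                                thresholds = c(high_gamma = thr))
    want <- oracle_local_maxima(v, thr)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      want_mm <- (want - 1) * 3
      got_mm <- as.matrix(got[c("x", "y", "z")])
      expect_equal(got_mm[order(got_mm[, 1], got_mm[, 2], got_mm[, 3]), ,
                          drop = FALSE],
                   want_mm[order(want_mm[, 1], want_mm[, 2], want_mm[, 3]), ,
                           drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("raising the threshold never increases the peak count", {
  set.seed(42)
  v <- array(rnorm(12^3, mean = 1), dim = c(12, 12, 12))
  vol <- make_volume(v)
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(thr)
    nrow(extract_local_maxima(vol, "alpha", thresholds = c(alpha = thr))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  pk <- extract_local_maxima(vol, "alpha", thresholds = c(alpha = 1.5))
  expect_true(all(pk$power >= 1.5))
})

test_that("extraction is equivariant under grid translation", {
  set.seed(3)
  v <- array(rnorm(8^3), dim = c(8, 8, 8))
  p1 <- extract_local_maxima(make_volume(v), "high_gamma")
  p2 <- extract_local_maxima(make_volume(v, origin = c(10, -5, 2)),
                             "high_gamma")
  expect_equal(p2$x, p1$x + 10)
  expect_equal(p2$y, p1$y - 5)
  expect_equal(p2$z, p1$z + 2)
})

test_that("merge_peaks concatenates without deduplication", {
  a <- random_peak_table(3, seed = 1)
  b <- random_peak_table(4, seed = 2)
  merged <- merge_peaks(list(a, b))
  expect_equal(nrow(merged), 7L)

  # identical peaks from different bands are both retained
  dup1 <- a[1, ]; dup2 <- a[1, ]; dup2$band <- "beta"; dup1$band <- "alpha"
  m2 <- merge_peaks(list(dup1, dup2))
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$x[1], m2$x[2])

  # 12 conditions x 4 bands totals correctly
  tabs <- list()
  total <- 0L
  for (ci in 1:12) for (band in band_levels()) {
    n <- sample(0:5, 1)
    if (n == 0) next
    t <- random_peak_table(n, seed = ci * 10 + match(band, band_levels()))
    t$condition <- sprintf("c%d", ci); t$band <- band
    tabs[[length(tabs) + 1L]] <- t
    total <- total + n
  }
  expect_equal(nrow(merge_peaks(tabs)), total)

  b$subject <- "someone_else"
  expect_error(merge_peaks(list(a, b)), "one subject")
})

test_that("affine registration of peaks matches direct matrix multiplication", {
  tab <- as_peak_table(random_peak_table(10, seed = 9))
  expect_equal(as.data.frame(to_talairach(tab, diag(4))),
               as.data.frame(tab))

  shift <- diag(4); shift[1, 4] <- 5
  one <- tab[1, ]; one$x <- 1; one$y <- 2; one$z <- 3
  got <- to_talairach(as_peak_table(one), shift)
  expect_equal(unname(unlist(got[c("x", "y", "z")])), c(6, 2, 3))

  set.seed(8)
  aff <- diag(4)
  aff[1:3, 1:4] <- aff[1:3, 1:4] + matrix(rnorm(12, sd = 0.2), 3, 4)
  got <- to_talairach(tab, aff)
  want <- t(aff %*% rbind(t(peak_coords(tab)), 1))[, 1:3]
  expect_equal(as.matrix(got[c("x", "y", "z")]), want, ignore_attr = TRUE)
  expect_equal(got$power, tab$power)

  sing <- diag(4); sing[1, 1] <- 0
  expect_error(to_talairach(tab, sing), "singular")
})
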