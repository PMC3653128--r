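one_region_spec <- function(..., conditions = "c1", bands = "alpha",
                            ppc = 5L, spread = 2, background = 0L,
                            jitter = 0, seed = 7L) {
  simulation_spec(
    data.frame(label = "R1", hemisphere = "left", x = 10, y = -20, z = 30,
               spread_mm = spread, peaks_per_condition = as.integer(ppc)),
    n_subjects = 2L, subject_jitter_mm = jitter, conditions = conditions,
    bands = bands, background_rate = as.integer(background),
    rng_seed = seed, ...)
}

test_that("peak counts follow regions x conditions x bands x rate exactly", {
  spec <- one_region_spec()
  pk <- simulate_subject_peaks(spec, 1)
  expect_equal(nrow(pk), 5L)

  spec <- one_region_spec(conditions = sprintf("c%d", 1:12),
                          bands = band_levels(), ppc = 2L, background = 3L)
  pk <- simulate_subject_peaks(spec, 1)
  expect_equal(nrow(pk), 2L * 12L * 4L + 3L * 12L)
  expect_s3_class(pk, "peak_table")
})

test_that("simulation is reproducible and subject-dependent", {
  spec <- default_simulation_spec(rng_seed = 5)
  a <- simulate_subject_peaks(spec, 1)
  b <- simulate_subject_peaks(spec, 1)
  expect_identical(a, b)
  c <- simulate_subject_peaks(spec, 2)
  expect_false(identical(a$x, c$x))
})

test_that("degenerate spread concentrates peaks at the subject centre", {
  spec <- one_region_spec(spread = 0.001, jitter = 0)
  pk <- simulate_subject_peaks(spec, 1)
  d <- sqrt((pk$x - 10)^2 + (pk$y + 20)^2 + (pk$z - 30)^2)
  expect_true(all(d < 0.01))
})

test_that("region scatter has the planted mean and spread", {
  spec <- one_region_spec(ppc = 10000L, spread = 3, jitter = 0)
  pk <- simulate_subject_peaks(spec, 1)
  ctr <- colMeans(peak_coords(pk))
  expect_lt(sqrt(sum((ctr - c(10, -20, 30))^2)), 0.2)
  sds <- apply(peak_coords(pk), 2, sd)
  expect_true(all(abs(sds - 3) / 3 < 0.05))
})

test_that("simulated powers stay above their band thresholds", {
  spec <- default_simulation_spec(rng_seed = 3)
  pk <- simulate_subject_peaks(spec, 1)
  thr <- default_band_thresholds()[pk$band]
  expect_true(all(pk$power >= thr))
  expect_true(all(pk$power <= thr + 2))
})

test_that("simulated volumes compose with peak extraction", {
  # no regions, zero noise: all-zero volume, no peaks
  spec <- simulation_spec(
    data.frame(label = character(), hemisphere = character(),
               x = numeric(), y = numeric(), z = numeric(),
               spread_mm = numeric(), peaks_per_condition = integer()),
    n_subjects = 1L, background_rate = 1L, noise_sd = 0, rng_seed = 1)
  vol <- simulate_volume(spec, 1, "alpha")
  expect_true(all(vol$values == 0))
  expect_equal(nrow(extract_local_maxima(vol, "alpha")), 0L)

  # one noiseless region: exactly one peak at the nearest voxel centre
  spec <- one_region_spec(noise_sd = 0)
  vol <- simulate_volume(spec, 1, "alpha")
  pk <- extract_local_maxima(vol, "alpha")
  expect_equal(nrow(pk), 1L)
  expect_true(all(abs(unlist(pk[c("x", "y", "z")]) - c(10, -20, 30)) <= 1.5))

  # centre placed exactly on a voxel centre is recovered exactly
  bb <- talairach_bounding_box()
  ctr <- bb[1, ] + 3 * c(20, 30, 20)
  spec2 <- simulation_spec(
    data.frame(label = "R1", hemisphere = "left", x = ctr[1], y = ctr[2],
               z = ctr[3], spread_mm = 4, peaks_per_condition = 1L),
    n_subjects = 1L, subject_jitter_mm = 0, background_rate = 0L,
    noise_sd = 0, rng_seed = 1)
  pk2 <- extract_local_maxima(simulate_volume(spec2, 1, "alpha"), "alpha")
  expect_equal(nrow(pk2), 1L)
  expect_equal(unname(unlist(pk2[c("x", "y", "z")])), unname(ctr))
})

test_that("volume noise is seeded per condition and band", {
  spec <- one_region_spec()
  v1 <- simulate_volume(spec, 1, "alpha", condition = "c1")
  v2 <- simulate_volume(spec, 1, "alpha", condition = "c1")
  expect_identical(v1$values, v2$values)
})

test_that("empty simulations are rejected", {
  expect_error(simulation_spec(
    data.frame(label = character(), hemisphere = character(),
               x = numeric(), y = numeric(), z = numeric(),
               spread_mm = numeric(), peaks_per_condition = integer()),
    background_rate = 0L), "at least one region or background")
})
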