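# synthetic sessions for map analysis: uniform grid trajectory plus
# hand-placed spike positions
synth_session <- function(spikes_xy, duration_s = 160, n_grid = 40) {
  ar <- arena()
  g <- seq(0.0125, 0.9875, length.out = n_grid)
  traj <- tibble::tibble(
    time_s = seq(0, duration_s - 0.1, 0.1),
    x = rep(g, length.out = duration_s * 10),
    y = rep(rep(g, each = n_grid), length.out = duration_s * 10),
    heading = 0)
  list(arena = ar, trajectory = traj,
       somatic_spikes = tibble::tibble(x = spikes_xy[, 1], y = spikes_xy[, 2]),
       config = list(dt_env = 0.1))
}

test_that("rate maps are occupancy-normalized and masked", {
  s <- synth_session(matrix(numeric(0), 0, 2))
  m <- rate_map(s, n_bins = 10, min_occupancy = 0.1)
  expect_equal(sum(m$occupancy_s), 160, tolerance = 0.1)
  expect_true(all(m$rate_hz[!is.na(m$rate_hz)] == 0))
  expect_error(field_centroid_and_size(m), "no positive rates")
  # uniform spikes + uniform occupancy: flat map (low coefficient of variation)
  set.seed(2)
  n <- 12000
  s2 <- synth_session(cbind(runif(n), runif(n)))
  m2 <- rate_map(s2, n_bins = 10, min_occupancy = 0.1)
  r <- m2$rate_hz[!is.na(m2$rate_hz)]
  expect_lt(sd(r) / mean(r), 0.2)
})

test_that("field centroid and size recover synthetic structure", {
  # single-bin spike mass
  s <- synth_session(matrix(rep(c(0.525, 0.525), 30), ncol = 2, byrow = TRUE))
  m <- rate_map(s, n_bins = 20, min_occupancy = 0.05)
  f <- field_centroid_and_size(m)
  expect_equal(unname(f$centroid), c(0.525, 0.525), tolerance = 0.026)
  expect_equal(f$area_bins, 1)
  # symmetric Gaussian bump: centroid within one bin of the center
  set.seed(3)
  s2 <- synth_session(cbind(rnorm(2000, 0.4, 0.08), rnorm(2000, 0.6, 0.08)))
  m2 <- rate_map(s2, n_bins = 20, min_occupancy = 0.05)
  f2 <- field_centroid_and_size(m2)
  expect_lt(max(abs(f2$centroid - c(0.4, 0.6))), 0.05)
  # field detection is invariant to uniform rate scaling
  m3 <- m2
  m3$rate_hz <- 5 * m3$rate_hz
  f3 <- field_centroid_and_size(m3)
  expect_equal(f3$centroid, f2$centroid)
  expect_equal(f3$area_bins, f2$area_bins)
})

test_that("rate-map rotation correlation peaks at the true angle", {
  set.seed(4)
  # asymmetric bump away from the center
  a <- synth_session(cbind(rnorm(2000, 0.25, 0.06), rnorm(2000, 0.75, 0.06)))
  # its 90-degree CCW image about the arena center is at (0.25, 0.25)
  b <- synth_session(cbind(rnorm(2000, 0.25, 0.06), rnorm(2000, 0.25, 0.06)))
  ma <- rate_map(a, n_bins = 10, min_occupancy = 0.05)
  mb <- rate_map(b, n_bins = 10, min_occupancy = 0.05)
  expect_gt(rotation_test(ma, mb, 90), rotation_test(ma, mb, 0))
  expect_gt(rotation_test(ma, mb, 90), 0.5)
  # identical maps at angle 0: perfect correlation
  expect_equal(rotation_test(ma, ma, 0), 1)
  # independent random maps: near-zero correlation
  set.seed(5)
  r1 <- synth_session(cbind(runif(400), runif(400)))
  r2 <- synth_session(cbind(runif(400), runif(400)))
  expect_lt(abs(rotation_test(rate_map(r1, n_bins = 20, min_occupancy = 0.05),
                              rate_map(r2, n_bins = 20, min_occupancy = 0.05),
                              0)), 0.2)
})

test_that("rate maps are equivariant under rigid rotation of the data", {
  set.seed(6)
  xy <- cbind(rnorm(1500, 0.3, 0.07), rnorm(1500, 0.7, 0.07))
  rot90 <- cbind(0.5 - (xy[, 2] - 0.5), 0.5 + (xy[, 1] - 0.5))
  m1 <- rate_map(synth_session(xy), n_bins = 10, min_occupancy = 0.05)
  m2 <- rate_map(synth_session(rot90), n_bins = 10, min_occupancy = 0.05)
  expect_gt(rotation_test(m1, m2, 90), 0.9)
})

test_that("the remapping statistic measures centroid separation", {
  set.seed(7)
  a <- synth_session(cbind(rnorm(1000, 0.25, 0.05), rnorm(1000, 0.8, 0.05)))
  b <- synth_session(cbind(rnorm(1000, 0.75, 0.05), rnorm(1000, 0.2, 0.05)))
  ma <- rate_map(a, n_bins = 20, min_occupancy = 0.05)
  mb <- rate_map(b, n_bins = 20, min_occupancy = 0.05)
  expect_equal(remap_test(ma, ma), 0)
  d <- remap_test(ma, mb)
  expect_equal(d, sqrt(0.5^2 + 0.6^2), tolerance = 0.1)
  empty <- rate_map(synth_session(matrix(numeric(0), 0, 2)),
                    n_bins = 10, min_occupancy = 0.05)
  expect_error(remap_test(ma, empty), "no positive rates")
})

test_that("plot methods return ggplot objects", {
  set.seed(8)
  s <- synth_session(cbind(runif(50), runif(50)))
  m <- rate_map(s, n_bins = 10, min_occupancy = 0.05)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(fx_control()), "ggplot")
  expect_s3_class(plot_weight_traces(fx_learning()), "ggplot")
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(tidy(m)), 100)
})
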