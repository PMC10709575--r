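test_that("trajectories are reproducible, bounded, and cover the arena", {
  ar <- arena()
  t1 <- make_trajectory(ar, 60, seed = 5)
  t2 <- make_trajectory(ar, 60, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$x >= 0 & t1$x <= 1 & t1$y >= 0 & t1$y <= 1))
  expect_true(all(t1$heading >= 0 & t1$heading < 360))
  t0 <- make_trajectory(ar, 10, speed = 0, seed = 1)
  expect_equal(diff(range(t0$x)), 0)
  # ergodicity smoke test: 1e4 steps cover > 80% of a coarse grid
  tl <- make_trajectory(ar, 1000, seed = 3)
  bins <- table(cut(tl$x, seq(0, 1, 0.1)), cut(tl$y, seq(0, 1, 0.1)))
  expect_gt(mean(bins > 0), 0.8)
})

test_that("visibility respects field of view, range, and resolution", {
  ar <- arena()
  vf <- visual_field()
  red <- ar$objects[ar$objects$object_id == "red", ]
  # at (0.1, 0.1) facing 258 deg: directly away from the red bar, and the
  # blue bar lies outside the 90 deg field of view
  expect_length(visible_features(0.1, 0.1, 258, ar, vf), 0)
  # close (within the foveal range) and facing, with the whole bar inside
  # the 90-degree field of view: all features of that object resolvable
  near_x <- red$x
  near_y <- red$y - 0.3
  vis <- visible_features(near_x, near_y, 90, ar, vf)
  expect_setequal(vis, ar$features$feature_id[ar$features$object_id == "red"])
  # rigid-motion invariance: rotate arena and agent jointly
  ang <- 90
  ar2 <- rotate_arena(ar, ang)
  c0 <- ar$side_length / 2
  th <- ang * pi / 180
  x2 <- c0 + cos(th) * (near_x - c0) - sin(th) * (near_y - c0)
  y2 <- c0 + sin(th) * (near_x - c0) + cos(th) * (near_y - c0)
  vis2 <- visible_features(x2, y2, 90 + ang, ar2, vf)
  expect_setequal(vis2, vis)
})

test_that("arena rotation is a rigid group action", {
  ar <- arena()
  expect_equal(rotate_arena(ar, 0)$features$fx, ar$features$fx)
  full <- rotate_arena(ar, 360)
  expect_equal(full$features$fx, ar$features$fx, tolerance = 1e-12)
  twice <- rotate_arena(rotate_arena(ar, 90), 90)
  once <- rotate_arena(ar, 180)
  expect_equal(twice$features$fx, once$features$fx, tolerance = 1e-12)
  expect_equal(twice$features$fy, once$features$fy, tolerance = 1e-12)
})

test_that("presynaptic rates are a pure function of the visible set", {
  syn <- place_cue_synapses(fx_neuron(), fx_arena())
  r0 <- presynaptic_rates(character(0), syn)
  expect_true(all(r0$rate_hz == 3))
  red_feats <- fx_arena()$features$feature_id[
    fx_arena()$features$object_id == "red"]
  r1 <- presynaptic_rates(red_feats, syn)
  expect_true(all(r1$rate_hz[syn$object_id == "red"] == 80))
  expect_true(all(r1$rate_hz[syn$object_id == "blue"] == 3))
  r2 <- presynaptic_rates(fx_arena()$features$feature_id, syn)
  expect_true(all(r2$rate_hz == 80))
  dup <- syn
  dup$feature_id[2] <- dup$feature_id[1]
  expect_error(presynaptic_rates(character(0), dup), "bijective")
})

test_that("the Poisson generator recovers its configured rates", {
  set.seed(123)
  expect_length(poisson_spike_train(
    tibble::tibble(t0_ms = 0, t1_ms = 1e5, rate_hz = 0)), 0)
  # 80 Hz over 100 s: count within 4 * sqrt(8000) of 8000
  n80 <- length(poisson_spike_train(
    tibble::tibble(t0_ms = 0, t1_ms = 1e5, rate_hz = 80)))
  expect_lt(abs(n80 - 8000), 4 * sqrt(8000))
  # empirical 3 Hz over 1000 s within ~3 SE
  n3 <- length(poisson_spike_train(
    tibble::tibble(t0_ms = 0, t1_ms = 1e6, rate_hz = 3)))
  expect_lt(abs(n3 / 1000 - 3), 0.35)
  # dispersion: variance/mean of per-second counts near 1 at both rates
  for (r in c(3, 80)) {
    tr <- poisson_spike_train(tibble::tibble(t0_ms = 0, t1_ms = 2e5,
                                             rate_hz = r))
    counts <- tabulate(floor(tr / 1000) + 1, nbins = 200)
    expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)
  }
  expect_error(poisson_spike_train(tibble::tibble(t0_ms = 1, t1_ms = 1,
                                                  rate_hz = 3)), "t1 > t0")
})
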