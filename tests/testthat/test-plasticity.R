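test_that("the depression branch is a Gaussian window centered at M", {
  p <- stdp_params()
  expect_equal(depression_update(0, -24), 0)
  # maximal shrinkage at delta = M, with the closed-form multiplier
  mult_at_M <- 1 - p$d / (p$V * sqrt(2 * pi))
  expect_equal(depression_update(1, p$M), mult_at_M)
  grid <- seq(-100, -0.5, by = 0.1)
  mult <- depression_update(1, grid)
  expect_equal(grid[which.min(mult)], p$M)
  expect_equal(depression_update(1, -200), 1, tolerance = 1e-9)
  expect_error(depression_update(1, 0), "t_post")
  expect_error(depression_update(1, 5), "t_post")
})

test_that("the potentiation branch is soft-bounded with e-folding tau", {
  p <- stdp_params(g_peak_max = 3)
  g0 <- 1
  head <- p$g_peak_max - g0
  expect_equal(potentiation_update(head, 1, g0, p), head)   # saturated
  expect_equal(potentiation_update(0.5, 1e6, g0, p), 0.5)   # vanishing
  expect_equal(potentiation_update(0, p$tau, g0, p), head * exp(-1))
  expect_error(potentiation_update(0, -1, g0, p), "t_post")
  # increments decay with e-folding tau: log-linear in delta
  d <- c(1, 3, 5, 9)
  inc <- vapply(d, function(x) potentiation_update(0, x, g0, p), 0)
  slopes <- diff(log(inc)) / diff(d)
  expect_equal(slopes, rep(-1 / p$tau, 3), tolerance = 1e-10)
})

test_that("event pairing follows the nearest-neighbor rule", {
  p <- stdp_params(g_peak_max = 3)
  # first-ever pre: history only
  r <- on_spike_events(tibble::tibble(time_ms = 10, type = "pre"), 1, 3, p)
  expect_equal(r$A_uS, 0)
  # pre@10, post@12: one potentiation at delta = +2
  r <- on_spike_events(tibble::tibble(time_ms = c(10, 12),
                                      type = c("pre", "post")), 1, 3, p)
  expect_equal(r$A_uS[2], 2 * exp(-2 / p$tau))
  # post@10, pre@34: one depression at delta = -24 (maximal window)
  r <- on_spike_events(tibble::tibble(time_ms = c(5, 7, 10, 34),
                                      type = c("pre", "post", "post", "pre")),
                       1, 3, p)
  A_before <- r$A_uS[3]
  expect_equal(r$A_uS[4], A_before * (1 - p$d / (p$V * sqrt(2 * pi))))
  expect_error(on_spike_events(tibble::tibble(time_ms = c(5, 4),
                                              type = c("pre", "post")),
                               1, 3, p), "order")
})

test_that("weights stay bounded for arbitrary event streams", {
  p <- stdp_params(g_peak_max = 3)
  set.seed(11)
  for (rep in 1:20) {
    n <- 200
    ev <- tibble::tibble(time_ms = sort(runif(n, 0, 1e4)),
                         type = sample(c("pre", "post"), n, TRUE))
    r <- on_spike_events(ev, 1, 3, p)
    expect_true(all(r$g_peak_uS >= 1 - 1e-12))
    expect_true(all(r$g_peak_uS <= 3 + 1e-12))
  }
  # depression-only sequences are non-increasing in A
  ev <- tibble::tibble(time_ms = c(0, sort(runif(50, 10, 5e3))),
                       type = c("post", rep("pre", 50)))
  r <- on_spike_events(ev, 1, 3, p, A0 = 1.5)
  expect_true(all(diff(r$A_uS) <= 1e-12))
  # alternating pre->post potentiation converges monotonically to the bound
  ev <- tibble::tibble(time_ms = as.numeric(rbind(seq(0, 980, 20),
                                                  seq(1, 981, 20))),
                       type = rep(c("pre", "post"), 50))
  r <- on_spike_events(ev, 1, 3, p)
  A <- r$A_uS[r$type == "post"]
  expect_true(all(diff(A) >= -1e-12))
  expect_lt(abs(A[length(A)] - 2), 0.05)
})

test_that("the engine applies the same rule as the reference processor", {
  # force dendritic spikes with brief strong current pulses into one oblique
  # while driving its synapse with a fixed presynaptic train; the engine's
  # final weight must match the reference event processor applied to the
  # events the engine actually recorded
  nrn <- fx_neuron()
  w <- fx_weights()[1, ]
  pre <- c(100, 300, 520, 900, 1400, 1410)
  pulses <- data.frame(compartment_id = w$dendrite_id,
                       onset_ms = c(105, 700, 1418), duration_ms = 4,
                       amplitude_nA = 1.5)
  out <- simulate_neuron(nrn, 2000, injections = pulses, synapses = w,
                         spike_trains = setNames(list(pre), w$synapse_id),
                         probes = w$dendrite_id, dt = 0.05, plasticity = TRUE)
  posts <- out$dend_spikes[[1]]
  expect_gt(length(posts), 0)
  ev <- dplyr::bind_rows(
    tibble::tibble(time_ms = pre, type = "pre"),
    tibble::tibble(time_ms = posts, type = "post")) |>
    dplyr::arrange(time_ms, type == "post")  # ties: pre before post
  ref <- on_spike_events(ev, w$g0_peak_uS, w$g_peak_max_uS,
                         stdp_params(g_peak_max = w$g_peak_max_uS))
  expect_equal(out$A_final[1], ref$A_uS[nrow(ref)], tolerance = 1e-6)
})

test_that("dendritic spike times delegate to the -10 mV crossing rule", {
  expect_length(dendritic_spike_times(rep(-60, 50)), 0)
  plateau <- c(rep(-60, 10), rep(0, 20), rep(-60, 10))
  expect_length(dendritic_spike_times(plateau), 1)
  two <- c(rep(-60, 5), rep(0, 5), rep(-60, 5), rep(0, 5), rep(-60, 5))
  expect_length(dendritic_spike_times(two), 2)
})
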