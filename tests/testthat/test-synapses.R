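test_that("the AMPA waveform is a normalized double exponential", {
  p <- synapse_params()
  expect_equal(ampa_conductance(0, p, 1), 0)
  tp <- with(p, (ampa_rise * ampa_decay / (ampa_decay - ampa_rise)) *
               log(ampa_decay / ampa_rise))
  expect_equal(ampa_conductance(tp, p, 0.5), 0.5, tolerance = 1e-10)
  # numerical argmax agrees with the closed form
  tt <- seq(0, 5, 1e-4)
  expect_equal(tt[which.max(ampa_conductance(tt, p, 1))], tp, tolerance = 1e-3)
  expect_lt(ampa_conductance(20, p, 1), 1e-6)
  expect_error(ampa_conductance(-1, p), "non-negative")
})

test_that("conductances are non-negative and exactly linear in weight", {
  p <- synapse_params()
  tt <- seq(0, 30, 0.01)
  g1 <- ampa_conductance(tt, p, 1)
  expect_true(all(g1 >= 0))
  expect_equal(ampa_conductance(tt, p, 3.7), 3.7 * g1)
  gn <- placecellr:::nmda_conductance(tt, p, 2)
  expect_true(all(gn >= 0))
})

test_that("the magnesium block behaves as a voltage-dependent sigmoid", {
  expect_lt(mg_block(-100, 1), 0.1)
  expect_gt(mg_block(60, 1), 0.9)
  expect_equal(mg_block(-40, 0), 1)
  v <- seq(-120, 60, 1)
  expect_true(all(diff(mg_block(v, 1)) > 0))
  b <- mg_block(v, 1)
  expect_true(all(b > 0 & b <= 1))
})

test_that("synaptic current follows the driving force and spike history", {
  p <- synapse_params()
  expect_equal(synaptic_current(c(1, 2), V_local = 0, t = 5, g_peak = 1, p), 0)
  expect_equal(synaptic_current(numeric(0), -65, 10, 1, p), 0)
  expect_lt(synaptic_current(9, -65, 10, 1, p), 0)  # inward-negative
  # spikes older than 10 * nmda_decay are dropped
  expect_equal(synaptic_current(0, -65, 10 * p$nmda_decay + 1, 1, p), 0)
})

test_that("cue synapses map features to oblique dendrites bijectively", {
  syn <- place_cue_synapses(fx_neuron(), fx_arena())
  expect_equal(nrow(syn), 14)
  expect_equal(anyDuplicated(syn$dendrite_id), 0)
  expect_equal(anyDuplicated(syn$feature_id), 0)
  expect_equal(sort(unique(syn$object_id)), c("blue", "red"))
  expect_error(place_cue_synapses(build_neuron(neuron_config(), settle_ms = 0),
                                  arena(objects = tibble::tibble(
                                    object_id = "big", x = .5, y = .5,
                                    width = .4, height = .05,
                                    n_features = 20L))),
               "not enough oblique")
})

test_that("baseline calibration keeps background activation subthreshold", {
  nrn <- fx_neuron()
  w <- fx_weights()
  expect_true(all(w$g0_peak_uS > 0))
  expect_equal(w$g_peak_max_uS, nrn$config$synapse$g_max_factor * w$g0_peak_uS)
  # background-only run of the full model, same calibration seed family:
  # no somatic spikes and no dendritic threshold crossings
  set.seed(42)
  trains <- lapply(seq_len(nrow(w)), function(s)
    poisson_spike_train(tibble::tibble(t0_ms = 0, t1_ms = 10000, rate_hz = 3)))
  names(trains) <- w$synapse_id
  out <- simulate_neuron(nrn, 10000, synapses = w, spike_trains = trains,
                         probes = "soma", dt = 0.05)
  expect_length(out$soma_spikes, 0)
  expect_equal(sum(lengths(out$dend_spikes)), 0)
})

test_that("doubling a calibrated weight makes the 80 Hz probe spike", {
  nrn <- fx_neuron()
  w <- fx_weights()
  w2 <- w
  w2$g0_peak_uS[1] <- 2 * w$g0_peak_uS[1]
  w2$g_peak_max_uS[1] <- 2 * w$g_peak_max_uS[1]
  set.seed(7)
  trains <- c(list(poisson_spike_train(
    tibble::tibble(t0_ms = 0, t1_ms = 5000, rate_hz = 80))),
    rep(list(numeric(0)), nrow(w) - 1))
  names(trains) <- w$synapse_id
  out <- simulate_neuron(nrn, 5000, synapses = w2, spike_trains = trains,
                         probes = w$dendrite_id[1], dt = 0.05)
  expect_gte(length(out$dend_spikes[[1]]), 1)
})

test_that("single-synapse somatic EPSPs are comparable across dendrites", {
  nrn <- fx_neuron()
  w <- fx_weights()
  comps <- compartments(nrn)
  dd <- comps$path_distance_to_soma[match(w$dendrite_id, comps$id)]
  epsp <- vapply(seq_len(nrow(w)), function(i) {
    trains <- rep(list(numeric(0)), nrow(w))
    trains[[i]] <- 50
    names(trains) <- w$synapse_id
    o <- simulate_neuron(nrn, 250, synapses = w, spike_trains = trains,
                         probes = "soma", dt = 0.05, record_dt = 0.5)
    max(o$voltage[, 1]) - o$voltage[1, 1]
  }, 0)
  # position-compensated weights keep somatic peaks within the same order
  # of magnitude across the tree (distal synapses are calibrated to larger
  # local conductances, which here slightly overcompensates with distance)
  expect_lt(max(epsp) / min(epsp), 5)
  expect_true(all(epsp > 0))
})

test_that("weight tables survive a CSV roundtrip", {
  w <- fx_weights()
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, path, config_hash = "abc")
  w2 <- read_weights_csv(path)
  expect_equal(w2$g0_peak_uS, w$g0_peak_uS)
  expect_equal(w2$synapse_id, w$synapse_id)
  expect_equal(attr(w2, "config_hash"), "abc")
})
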