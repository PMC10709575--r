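# AMPA+NMDA synapse model on oblique dendrites: closed-form conductance
# waveforms, Mg block, cue-synapse placement and per-dendrite baseline-weight
# calibration.

#' Synaptic kinetic parameters
#'
#' @param ampa_rise,ampa_decay AMPA double-exponential time constants, ms.
#' @param nmda_rise,nmda_decay NMDA double-exponential time constants, ms.
#' @param reversal synaptic reversal potential, mV.
#' @param mg_concentration external Mg2+ concentration, mM.
#' @param mg_eta,mg_gamma Mg-block sigmoid constants (1/mM, 1/mV).
#' @param nmda_to_ampa_ratio NMDA peak conductance relative to AMPA.
#' @return a `synapse_params` list.
#' @export
synapse_params <- function(ampa_rise = 0.5, ampa_decay = 1.0,
                           nmda_rise = 5, nmda_decay = 50, reversal = 0,
                           mg_concentration = 1.0, mg_eta = 0.28,
                           mg_gamma = 0.062, nmda_to_ampa_ratio = 1.0) {
  p <- list(ampa_rise = ampa_rise, ampa_decay = ampa_decay,
            nmda_rise = nmda_rise, nmda_decay = nmda_decay,
            reversal = reversal, mg_concentration = mg_concentration,
            mg_eta = mg_eta, mg_gamma = mg_gamma,
            nmda_to_ampa_ratio = nmda_to_ampa_ratio)
  if (p$ampa_rise >= p$ampa_decay || p$nmda_rise >= p$nmda_decay) {
    abort("rise time constants must be smaller than decay time constants")
  }
  if (any(unlist(p[c(1, 2, 3, 4, 6)]) <= 0)) {
    abort("time constants and mg_concentration must be positive")
  }
  structure(p, class = "synapse_params")
}

dexp_norm <- function(rise, decay) {
  tp <- (rise * decay / (decay - rise)) * log(decay / rise)
  1 / (exp(-tp / decay) - exp(-tp / rise))
}

#' Double-exponential AMPA conductance waveform
#'
#' `g(t) = g_peak * norm * (exp(-t/decay) - exp(-t/rise))`, with `norm`
#' chosen so that the maximum over `t` equals `g_peak`.
#'
#' @param t_since_spike time since the presynaptic spike, ms (>= 0).
#' @param params a [synapse_params()] list.
#' @param g_peak peak conductance, uS.
#' @return conductance, uS (vectorized over `t_since_spike`).
#' @export
ampa_conductance <- function(t_since_spike, params = synapse_params(),
                             g_peak = 1) {
  if (any(t_since_spike < 0)) abort("t_since_spike must be non-negative")
  n <- dexp_norm(params$ampa_rise, params$ampa_decay)
  g_peak * n * (exp(-t_since_spike / params$ampa_decay) -
                  exp(-t_since_spike / params$ampa_rise))
}

nmda_conductance <- function(t_since_spike, params = synapse_params(),
                             g_peak = 1) {
  if (any(t_since_spike < 0)) abort("t_since_spike must be non-negative")
  n <- dexp_norm(params$nmda_rise, params$nmda_decay)
  g_peak * n * (exp(-t_since_spike / params$nmda_decay) -
                  exp(-t_since_spike / params$nmda_rise))
}

#' Voltage-dependent magnesium block of the NMDA conductance
#'
#' Sigmoid form `1 / (1 + eta * [Mg] * exp(-gamma * V))`: approaches 0 at
#' strongly hyperpolarized potentials, 1 at depolarized potentials, and 1 for
#' vanishing Mg.
#'
#' @param V membrane potential, mV (vectorized).
#' @param mg Mg2+ concentration, mM.
#' @param eta,gamma sigmoid constants.
#' @return unblocked fraction in (0, 1].
#' @export
mg_block <- function(V, mg = 1, eta = 0.28, gamma = 0.062) {
  1 / (1 + eta * mg * exp(-gamma * V))
}

#' Total synaptic current of one synapse
#'
#' Reference (closed-form) implementation summing AMPA and Mg-blocked NMDA
#' conductances over the recent presynaptic spike history:
#' `I = (g_AMPA + g_NMDA * mg_block(V)) * (V - reversal)` in nA
#' (inward-negative convention). Spikes older than `10 * nmda_decay` are
#' dropped.
#'
#' @param spike_times presynaptic spike times, ms.
#' @param V_local local membrane potential, mV.
#' @param t current time, ms.
#' @param g_peak effective peak conductance `g0 + A`, uS.
#' @param params a [synapse_params()] list.
#' @return current, nA.
#' @export
synaptic_current <- function(spike_times, V_local, t, g_peak,
                             params = synapse_params()) {
  dt <- t - spike_times
  dt <- dt[dt >= 0 & dt <= 10 * params$nmda_decay]
  if (length(dt) == 0) return(0)
  g <- sum(ampa_conductance(dt, params, g_peak)) +
    sum(nmda_conductance(dt, params, params$nmda_to_ampa_ratio * g_peak)) *
      mg_block(V_local, params$mg_concentration, params$mg_eta, params$mg_gamma)
  g * (V_local - params$reversal)
}

#' Place cue synapses on oblique dendrites
#'
#' One synapse per oblique dendrite; each synapse models the synchronous
#' activation of a group of inputs coding for one object feature. Features of
#' the arena's objects are assigned to obliques in an interleaved order over
#' path distance, so each object's features span the whole trunk.
#'
#' @param neuron a `ca1_neuron`.
#' @param arena an [arena()]; its features are mapped bijectively onto
#'   obliques (requires `n_oblique >=` number of features).
#' @return tibble: `synapse_id`, `feature_id`, `object_id`, `dendrite_id`,
#'   `g0_peak_uS` (NA until calibrated), `g_peak_max_uS`.
#' @export
place_cue_synapses <- function(neuron, arena) {
  feats <- arena$features
  obl <- neuron$compartments |>
    dplyr::filter(.data$region == "oblique") |>
    dplyr::arrange(.data$path_distance_to_soma)
  if (nrow(feats) > nrow(obl)) {
    abort("not enough oblique dendrites for the arena's features")
  }
  objs <- unique(feats$object_id)
  # interleave: object k takes obliques k, k + n_obj, k + 2 n_obj, ...
  ord <- order(match(feats$object_id, objs),
               as.integer(sub(".*_", "", feats$feature_id)))
  feats <- feats[ord, ]
  slot <- integer(nrow(feats))
  for (k in seq_along(objs)) {
    idx <- which(feats$object_id == objs[k])
    slot[idx] <- seq(k, by = length(objs), length.out = length(idx))
  }
  tibble::tibble(
    synapse_id = paste0("syn_", feats$feature_id),
    feature_id = feats$feature_id,
    object_id = feats$object_id,
    dendrite_id = obl$id[slot],
    g0_peak_uS = NA_real_,
    g_peak_max_uS = NA_real_)
}

#' Calibrate per-dendrite baseline synaptic weights
#'
#' For each synapse, finds the largest peak conductance on a geometric grid
#' (factor `grid_factor`) such that a fixed-seed probe run -- that synapse
#' alone, activated at the background rate for `duration_s` -- produces zero
#' crossings of the local dendritic spike threshold. This operationalizes
#' "just below the spiking threshold at background frequency" per dendrite,
#' compensating for position-dependent input resistance.
#'
#' @param neuron a `ca1_neuron`.
#' @param synapses synapse table from [place_cue_synapses()].
#' @param background_rate Hz (default 3, theta range).
#' @param dendritic_threshold mV.
#' @param seed calibration seed (one probe train per synapse, reproducible).
#' @param duration_s probe duration per synapse, s.
#' @param grid_factor geometric grid ratio.
#' @param g_floor smallest grid conductance, uS; calibration fails if even
#'   this spikes.
#' @return the synapse table with `g0_peak_uS` and `g_peak_max_uS` filled in.
#' @export
calibrate_baseline_weights <- function(neuron, synapses, background_rate = 3,
                                       dendritic_threshold = -10, seed = 42,
                                       duration_s = 10, grid_factor = 1.25,
                                       g_floor = 1e-5) {
  dur_ms <- duration_s * 1000
  gmax_factor <- neuron$config$synapse$g_max_factor
  ratio <- neuron$config$synapse$nmda_to_ampa_ratio
  coarse <- grid_factor^6
  grid_g <- function(k) g_floor * grid_factor^k

  probe_one <- function(i) {
    withr_seed <- seed + i
    set.seed(withr_seed)
    train <- poisson_spike_train(
      tibble::tibble(t0_ms = 0, t1_ms = dur_ms, rate_hz = background_rate))
    comp0 <- comp_index0(neuron, synapses$dendrite_id[i])
    spikes_at <- function(g) {
      syn <- list(comp = comp0, g0 = g, A0 = 0, gmax = gmax_factor * g,
                  nmda_ratio = ratio,
                  nmda_sat = neuron$config$synapse$nmda_saturation %||% 0,
                  ampa_sat = neuron$config$synapse$ampa_saturation %||% 0,
                  pre_times = train,
                  pre_offsets = c(0L, length(train)))
      out <- engine_call(neuron, dur_ms, dt = neuron$config$integration$dt_max,
                        synapses = syn, probes = integer(0), record_stride = 0L,
                        dend_threshold = dendritic_threshold)
      length(out$dend_spikes[[1]])
    }
    if (spikes_at(g_floor) > 0) {
      abort(paste0("calibration failed for ", synapses$synapse_id[i],
                   ": smallest grid conductance already spikes"))
    }
    # coarse ascent on the same geometric grid (stride grid_factor^6)
    k_lo <- 0
    repeat {
      k_hi <- k_lo + 6
      if (spikes_at(grid_g(k_hi)) > 0) break
      k_lo <- k_hi
      if (grid_g(k_lo) > 5) abort("calibration grid exhausted")
    }
    # fine ascent within the bracket
    k <- k_lo
    while (k + 1 <= k_hi && spikes_at(grid_g(k + 1)) == 0) k <- k + 1
    grid_g(k)
  }

  g0 <- purrr::map_dbl(seq_len(nrow(synapses)), probe_one)
  synapses$g0_peak_uS <- g0
  synapses$g_peak_max_uS <- gmax_factor * g0
  synapses
}

#' Export or import calibrated weights
#'
#' CSV with columns `synapse_id`, `dendrite_id`, `g0_peak_uS` (and, for
#' session exports, `A_uS`, `g_peak_uS`), preceded by a `# config_hash:`
#' comment for provenance.
#'
#' @param weights a synapse/weight tibble.
#' @param path file path.
#' @param config_hash provenance hash (computed from the neuron config if a
#'   neuron is supplied).
#' @return `write_weights_csv()` returns `path` invisibly;
#'   `read_weights_csv()` returns the tibble with the hash in attribute
#'   `config_hash`.
#' @export
write_weights_csv <- function(weights, path, config_hash = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(weights, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  first <- readLines(path, n = 1)
  hash <- sub("^# config_hash: ", "", first)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(out, "config_hash") <- hash
  out
}
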