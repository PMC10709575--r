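# Low-level wrapper around the compiled engine plus user-facing simulation
# helpers that return tidy traces.

# neuron: ca1_neuron; synapses: NULL or internal list (see as_engine_synapses);
# stim: matrix with columns comp0 (0-based), onset, dur, amp.
engine_call <- function(neuron, duration_ms, dt = NULL, synapses = NULL,
                        stim = NULL, probes = 0L, record_stride = NULL,
                        record_dt = 1, init = "rest", stdp = FALSE,
                        dend_threshold = NULL) {
  cfg <- neuron$config$integration
  dt <- dt %||% cfg$dt
  if (dt <= 0 || dt > cfg$dt_max) {
    abort(paste0("dt must be in (0, ", cfg$dt_max, "] ms"))
  }
  if (is.null(record_stride)) record_stride <- max(1L, round(record_dt / dt))
  if (is.null(stim)) stim <- matrix(0, 0, 4)
  syn <- synapses %||% list(comp = integer(0), g0 = numeric(0), A0 = numeric(0),
                            gmax = numeric(0), nmda_ratio = 1,
                            pre_times = numeric(0), pre_offsets = 0L)
  syn$stdp_on <- isTRUE(stdp)
  syn$pre_offsets <- as.integer(syn$pre_offsets)
  ctrl <- list(dt = dt, duration_ms = duration_ms, probes = as.integer(probes),
               record_stride = as.integer(record_stride),
               soma_comp = 0L,
               soma_threshold = cfg$soma_spike_threshold,
               dend_threshold = dend_threshold %||%
                 neuron$config$stdp$dendritic_spike_threshold)
  if (identical(init, "rest") && !is.null(neuron$rest)) {
    ctrl$v0 <- neuron$rest$v
    ctrl$gating0 <- neuron$rest$gating
  } else if (is.list(init)) {
    ctrl$v0 <- init$v
    ctrl$gating0 <- init$gating
  }
  engine_run(neuron$engine, syn, stim, ctrl)
}

comp_index0 <- function(neuron, ids) {
  idx <- match(ids, neuron$compartments$id)
  if (anyNA(idx)) abort(paste("unknown compartment id:", ids[is.na(idx)][1]))
  idx - 1L
}

stim_matrix <- function(neuron, injections) {
  if (is.null(injections) || nrow(injections) == 0) return(matrix(0, 0, 4))
  cbind(comp_index0(neuron, injections$compartment_id),
        injections$onset_ms, injections$duration_ms, injections$amplitude_nA)
}

#' Simulate the neuron for a fixed duration
#'
#' Integrates the cable + channel equations with optional current injections
#' and synapses, starting from the settled resting state. Voltage probes are
#' recorded at `record_dt` resolution.
#'
#' @param neuron a `ca1_neuron` from [build_neuron()].
#' @param duration_ms simulated time, ms.
#' @param injections `NULL` or a data frame with columns `compartment_id`,
#'   `onset_ms`, `duration_ms`, `amplitude_nA`.
#' @param synapses `NULL` or a calibrated synapse table (see
#'   [place_cue_synapses()]) together with `spike_trains`, a named list of
#'   presynaptic spike-time vectors (ms) per synapse.
#' @param spike_trains named list of numeric vectors, presynaptic spike times
#'   per synapse id.
#' @param probes compartment ids to record, or `"all"`.
#' @param dt integration step, ms; defaults to the neuron's configured step.
#' @param record_dt probe sampling interval, ms.
#' @param plasticity enable the STDP rule during the run.
#' @param init `"rest"` (default) or a list with `v` and `gating`.
#' @return list with `traces` (tibble: time_ms, compartment_id, voltage_mV),
#'   `soma_spikes` (ms), `dend_spikes` (named list, ms),
#'   `A_final`, `weight_log`, `state` (final v/gating), `gating_range`.
#' @export
simulate_neuron <- function(neuron, duration_ms, injections = NULL,
                            synapses = NULL, spike_trains = NULL,
                            probes = "soma", dt = NULL, record_dt = 1,
                            plasticity = FALSE, init = "rest") {
  probe_ids <- if (identical(probes, "all")) neuron$compartments$id else probes
  syn <- if (!is.null(synapses)) {
    as_engine_synapses(neuron, synapses, spike_trains)
  }
  out <- engine_call(neuron, duration_ms, dt = dt, synapses = syn,
                     stim = stim_matrix(neuron, injections),
                     probes = comp_index0(neuron, probe_ids),
                     record_dt = record_dt, init = init, stdp = plasticity)
  v <- out$v
  colnames(v) <- probe_ids
  traces <- tibble::as_tibble(as.data.frame(v)) |>
    dplyr::mutate(time_ms = out$time_ms, .before = 1) |>
    tidyr::pivot_longer(-"time_ms", names_to = "compartment_id",
                        values_to = "voltage_mV")
  dend <- out$dend_spikes
  if (!is.null(synapses)) names(dend) <- synapses$synapse_id
  list(traces = traces,
       voltage = v, time_ms = out$time_ms,
       soma_spikes = out$soma_spikes,
       dend_spikes = dend,
       A_final = out$A_final,
       weight_log = weight_log_tibble(out$weight_log, synapses),
       state = list(v = out$v_final, gating = out$gating_final),
       gating_range = c(out$gating_min, out$gating_max))
}

weight_log_tibble <- function(wl, synapses) {
  if (is.null(wl) || nrow(wl) == 0) {
    return(tibble::tibble(time_ms = numeric(0), synapse_id = character(0),
                          A_uS = numeric(0), event_type = character(0)))
  }
  tibble::tibble(
    time_ms = wl[, 1],
    synapse_id = if (!is.null(synapses)) synapses$synapse_id[wl[, 2]]
                 else as.character(wl[, 2]),
    A_uS = wl[, 3],
    event_type = ifelse(wl[, 4] > 0, "potentiation", "depression"))
}

#' Advance the neuron state by a single integration step
#'
#' One backward-Euler step of the cable equations with per-compartment
#' synaptic and injected currents held constant over the step. Mostly useful
#' for fine-grained inspection; sessions use [simulate_neuron()].
#'
#' @param neuron a `ca1_neuron`.
#' @param synaptic_currents,injected_currents numeric vectors, nA per
#'   compartment (recycled scalars allowed).
#' @param dt step, ms (must be in (0, dt_max]).
#' @param state list with `v` and `gating`; defaults to the resting state.
#' @return updated state list with elements `v` and `gating`.
#' @export
advance_state <- function(neuron, synaptic_currents = 0, injected_currents = 0,
                          dt = NULL, state = NULL) {
  n <- nrow(neuron$compartments)
  cur <- rep_len(synaptic_currents, n) + rep_len(injected_currents, n)
  nz <- which(cur != 0)
  dt <- dt %||% neuron$config$integration$dt
  stim <- if (length(nz)) cbind(nz - 1L, 0, 2 * dt, cur[nz]) else NULL
  out <- engine_call(neuron, duration_ms = dt, dt = dt, stim = stim,
                     probes = integer(0), record_stride = 0L,
                     init = state %||% "rest")
  list(v = out$v_final, gating = out$gating_final)
}

#' Detect upward threshold crossings in a voltage trace
#'
#' Returns the times at which the trace crosses `threshold` from below. After
#' a crossing, the trace must first fall back below the threshold before a
#' new event is counted (single-excursion rule).
#'
#' @param trace data frame with columns `time_ms` and `voltage_mV`, or a
#'   numeric voltage vector (then supply `time_ms`).
#' @param threshold mV.
#' @param time_ms sample times when `trace` is a bare vector.
#' @return numeric vector of crossing times, ms.
#' @export
detect_threshold_crossings <- function(trace, threshold, time_ms = NULL) {
  if (is.data.frame(trace)) {
    time_ms <- trace$time_ms
    v <- trace$voltage_mV
  } else {
    v <- trace
    if (is.null(time_ms)) time_ms <- seq_along(v)
  }
  if (length(v) == 0) abort("empty voltage trace")
  above <- v >= threshold
  up <- which(above & !c(TRUE, above[-length(above)]))
  time_ms[up]
}
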