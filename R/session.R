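# Environment-coupled simulation sessions: control (no plateau), learning
# (plateau triggered by viewing the rewarded object) and recall (plasticity
# left free after learning).

#' Session configuration
#'
#' @param mode `"control_no_plateau"`, `"learning_with_plateau"` or
#'   `"recall"`.
#' @param rewarded_object object id the plateau is tied to (required in
#'   learning mode).
#' @param duration_s session length, s. Defaults: 60 (control), 120
#'   (learning), 300 (recall).
#' @param seeds list with `trajectory`, `synaptic`, `calibration` integer
#'   seeds.
#' @param plasticity_enabled apply the STDP rule during the session
#'   (default TRUE; the rule is never blocked in the canonical experiments).
#' @param dt neural integration step, ms.
#' @param dt_env environment step, s.
#' @param speed,turn_sd_deg agent random-walk parameters.
#' @param cue_rate,background_rate presynaptic rates, Hz.
#' @param fov,max_range visual-field parameters (length units follow the
#'   arena).
#' @param min_visible_features features of the rewarded object that must be
#'   simultaneously visible to trigger the plateau (learning mode). The
#'   default `Inf` requires the whole object (clamped to its feature count).
#' @param trigger_refractory_s minimum interval between successive plateau
#'   onsets; sightings during the refractory period do not retrigger.
#' @param target_depol plateau amplitude calibration target, mV above rest.
#' @param record_dt probe sampling interval, ms.
#' @param probes compartment ids to record (default: soma plus one dendrite
#'   per object).
#' @return a `session_config` list.
#' @export
session_config <- function(mode = c("control_no_plateau",
                                    "learning_with_plateau", "recall"),
                           rewarded_object = NULL, duration_s = NULL,
                           seeds = list(trajectory = 1, synaptic = 2,
                                        calibration = 42),
                           plasticity_enabled = TRUE, dt = 0.05, dt_env = 0.1,
                           speed = 0.08, turn_sd_deg = 4, cue_rate = 80,
                           background_rate = 3, fov = 90, max_range = 1.2,
                           min_visible_features = 6, target_depol = 32,
                           trigger_refractory_s = 60,
                           record_dt = 1, probes = NULL) {
  mode <- match.arg(mode)
  if (mode == "learning_with_plateau" && is.null(rewarded_object)) {
    abort("learning mode requires a rewarded_object")
  }
  duration_s <- duration_s %||% switch(mode, control_no_plateau = 60,
                                       learning_with_plateau = 120,
                                       recall = 300)
  structure(list(mode = mode, rewarded_object = rewarded_object,
                 duration_s = duration_s, seeds = seeds,
                 plasticity_enabled = plasticity_enabled, dt = dt,
                 dt_env = dt_env, speed = speed, turn_sd_deg = turn_sd_deg,
                 cue_rate = cue_rate, background_rate = background_rate,
                 fov = fov, max_range = max_range,
                 min_visible_features = min_visible_features,
                 trigger_refractory_s = trigger_refractory_s,
                 target_depol = target_depol, record_dt = record_dt,
                 probes = probes), class = "session_config")
}

#' Plateau trigger decision from the visibility stream
#'
#' Returns the environment steps at which the rewarded object enters the
#' visual field (at least `min_visible_features` of its features become
#' visible on a rising edge), thinned by the refractory lockout; `NA` if it
#' never happens.
#'
#' @param vis logical visibility matrix (steps x features).
#' @param arena the [arena()].
#' @param rewarded_object object id.
#' @param min_visible_features count threshold (Inf = all features).
#' @param refractory_steps minimum separation between onsets, environment steps.
#' @return integer vector of step indices, or NA.
#' @export
reward_trigger <- function(vis, arena, rewarded_object,
                           min_visible_features = Inf,
                           refractory_steps = Inf) {
  cols <- which(arena$features$object_id == rewarded_object)
  if (length(cols) == 0) abort("unknown rewarded object")
  need <- min(min_visible_features, length(cols))
  hits <- rowSums(vis[, cols, drop = FALSE]) >= need
  # the object must *enter* the field: rising edge of the visibility signal
  edge <- which(hits & !c(TRUE, hits[-length(hits)]))
  if (length(edge) == 0) return(NA_integer_)
  onsets <- edge[1]
  for (e in edge[-1]) {
    if (e - onsets[length(onsets)] >= refractory_steps) onsets <- c(onsets, e)
  }
  onsets
}

as_engine_synapses <- function(neuron, synapses, spike_trains, A0 = NULL) {
  if (anyNA(synapses$g0_peak_uS)) abort("synapse weights are not calibrated")
  trains <- lapply(synapses$synapse_id, function(id) {
    tr <- spike_trains[[id]] %||% numeric(0)
    sort(tr)
  })
  lens <- vapply(trains, length, 0L)
  list(comp = comp_index0(neuron, synapses$dendrite_id),
       g0 = synapses$g0_peak_uS,
       A0 = A0 %||% rep(0, nrow(synapses)),
       gmax = synapses$g_peak_max_uS,
       nmda_ratio = neuron$config$synapse$nmda_to_ampa_ratio,
       nmda_sat = neuron$config$synapse$nmda_saturation %||% 0,
       ampa_sat = neuron$config$synapse$ampa_saturation %||% 0,
       pre_times = as.numeric(unlist(trains)),
       pre_offsets = c(0L, cumsum(lens)))
}

#' Run an environment-coupled session
#'
#' Generates the trajectory and visibility stream at the environment step,
#' converts visibility into piecewise-constant presynaptic rates, samples
#' Poisson spike trains, triggers the plateau protocol in learning mode, and
#' co-simulates the neuron with event-driven STDP. Deterministic given the
#' seed triple.
#'
#' @param neuron a `ca1_neuron`.
#' @param arena an [arena()].
#' @param cfg a [session_config()].
#' @param weights calibrated synapse table (from
#'   [calibrate_baseline_weights()] or a learning session's `weights`); if
#'   `NULL` calibration is run (cached per configuration).
#' @param A0 optional initial plastic increments (recall after learning).
#' @param protocol optional pre-built [plateau_protocol()].
#' @return a `pc_session` object; see [tidy.pc_session()] for tabular views.
#' @export
run_session <- function(neuron, arena, cfg = session_config(), weights = NULL,
                        A0 = NULL, protocol = NULL) {
  vf <- visual_field(cfg$fov, cfg$max_range)
  if (is.null(weights)) {
    weights <- calibrated_weights(neuron, arena, seed = cfg$seeds$calibration)
  }

  traj <- make_trajectory(arena, cfg$duration_s, dt_env = cfg$dt_env,
                          speed = cfg$speed, turn_sd_deg = cfg$turn_sd_deg,
                          seed = cfg$seeds$trajectory)
  vis <- visibility_matrix(traj, arena, vf)

  # plateau trigger (learning mode): onsets at rising edges of rewarded-object
  # visibility, thinned by the refractory lockout; later onsets are dropped at
  # run time once the association has formed (all of the rewarded object's
  # synapses potentiated), modeling a reward signal that stops re-engaging
  # once the place association is consolidated
  plateau_onsets <- numeric(0)
  cand_steps <- integer(0)
  proto <- NULL
  if (cfg$mode == "learning_with_plateau") {
    refr <- (cfg$trigger_refractory_s %||% Inf) / cfg$dt_env
    steps <- reward_trigger(vis, arena, cfg$rewarded_object,
                            cfg$min_visible_features,
                            refractory_steps = refr)
    if (!anyNA(steps)) {
      cand_steps <- steps
      proto <- protocol %||% plateau_protocol(neuron)
      if (anyNA(proto$schedule$amplitude_nA)) {
        amp <- calibrate_plateau_amplitude(neuron, proto,
                                           target_depol = cfg$target_depol)
        proto$schedule$amplitude_nA <- amp
      }
    }
  }

  # piecewise-constant rates -> Poisson trains per synapse
  dur_ms <- cfg$duration_s * 1000
  step_ms <- cfg$dt_env * 1000
  t0 <- traj$time_s * 1000
  t1 <- pmin(t0 + step_ms, dur_ms)
  feat_vis <- vis[, match(weights$feature_id, colnames(vis)), drop = FALSE]
  set.seed(cfg$seeds$synaptic)
  trains <- lapply(seq_len(nrow(weights)), function(s) {
    rate <- ifelse(feat_vis[, s], cfg$cue_rate, cfg$background_rate)
    poisson_spike_train(tibble::tibble(t0_ms = t0, t1_ms = t1, rate_hz = rate))
  })
  names(trains) <- weights$synapse_id

  probe_ids <- cfg$probes %||% default_probes(neuron, weights)
  probe_idx <- comp_index0(neuron, probe_ids)

  # simulate in segments split at candidate plateau onsets so retriggering can
  # be gated on the weight state reached so far
  seg_bounds <- c(0, traj$time_s[cand_steps] * 1000, dur_ms)
  seg_bounds <- unique(pmin(seg_bounds, dur_ms))
  A_now <- A0 %||% rep(0, nrow(weights))
  state <- "rest"
  acc <- list(time = NULL, v = NULL, soma = NULL,
              dend = rep(list(numeric(0)), nrow(weights)), wlog = NULL)
  for (si in seq_len(length(seg_bounds) - 1)) {
    t_a <- seg_bounds[si]; t_b <- seg_bounds[si + 1]
    if (t_b <= t_a) next
    seg_stim <- matrix(0, 0, 4)
    n_rew <- sum(weights$object_id == cfg$rewarded_object)
    n_pot <- sum(A_now > 0.01 * weights$g0_peak_uS)
    if (si > 1 && n_pot < n_rew) {
      p_on <- shift_protocol(proto, 0)
      seg_stim <- protocol_stim(neuron, p_on)
      plateau_onsets <- c(plateau_onsets, t_a)
    }
    seg_trains <- lapply(trains, function(tr) tr[tr > t_a & tr <= t_b] - t_a)
    syn <- as_engine_synapses(neuron, weights, seg_trains, A0 = A_now)
    out <- engine_call(neuron, t_b - t_a, dt = cfg$dt, synapses = syn,
                       stim = seg_stim, probes = probe_idx,
                       record_dt = cfg$record_dt,
                       stdp = cfg$plasticity_enabled, init = state)
    state <- list(v = out$v_final, gating = out$gating_final)
    A_now <- out$A_final
    acc$time <- c(acc$time, out$time_ms[-1] + t_a)
    acc$v <- rbind(acc$v, out$v[-1, , drop = FALSE])
    acc$soma <- c(acc$soma, out$soma_spikes + t_a)
    for (s in seq_len(nrow(weights))) {
      acc$dend[[s]] <- c(acc$dend[[s]], out$dend_spikes[[s]] + t_a)
    }
    wl <- out$weight_log
    if (nrow(wl) > 0) wl[, 1] <- wl[, 1] + t_a
    acc$wlog <- rbind(acc$wlog, wl)
  }
  colnames(acc$v) <- probe_ids
  names(acc$dend) <- weights$synapse_id
  sim <- list(voltage = acc$v, time_ms = acc$time, soma_spikes = acc$soma,
              dend_spikes = acc$dend, A_final = A_now,
              weight_log = weight_log_tibble(acc$wlog, weights),
              gating_range = c(NA_real_, NA_real_))

  # spatial attribution of somatic spikes (nearest environment sample)
  spike_steps <- pmin(pmax(floor(sim$soma_spikes / step_ms) + 1, 1), nrow(traj))
  red_cols <- if (!is.null(cfg$rewarded_object)) {
    which(arena$features$object_id == cfg$rewarded_object)
  } else integer(0)
  somatic <- tibble::tibble(
    time_ms = sim$soma_spikes,
    x = traj$x[spike_steps], y = traj$y[spike_steps],
    rewarded_visible = if (length(red_cols)) {
      rowSums(vis[spike_steps, red_cols, drop = FALSE]) > 0
    } else NA)

  weights_out <- weights |>
    dplyr::mutate(A_uS = sim$A_final,
                  g_peak_uS = .data$g0_peak_uS + .data$A_uS)

  structure(list(
    somatic_spikes = somatic,
    dendritic_spikes = sim$dend_spikes,
    weights = weights_out,
    weight_log = sim$weight_log,
    trajectory = traj,
    visibility = vis,
    probes = list(time_ms = sim$time_ms, voltage = sim$voltage),
    plateau_onsets = plateau_onsets,
    gating_range = sim$gating_range,
    arena = arena, config = cfg), class = "pc_session")
}

repack_sim <- function(out, probe_ids, weights) {
  v <- out$v
  colnames(v) <- probe_ids
  dend <- out$dend_spikes
  names(dend) <- weights$synapse_id
  list(voltage = v, time_ms = out$time_ms, soma_spikes = out$soma_spikes,
       dend_spikes = dend, A_final = out$A_final,
       weight_log = weight_log_tibble(out$weight_log, weights),
       gating_range = c(out$gating_min, out$gating_max))
}

default_probes <- function(neuron, weights) {
  per_obj <- weights |>
    dplyr::group_by(.data$object_id) |>
    dplyr::slice(1) |>
    dplyr::pull("dendrite_id")
  c("soma", per_obj)
}

# cached full calibration for a neuron + arena configuration
calibrated_weights <- function(neuron, arena, seed = 42) {
  thr <- neuron$config$synapse$calibration_threshold %||% -10
  key <- rlang::hash(list("weights", neuron$config, arena$objects,
                          arena$features$feature_id, seed, thr))
  if (is.null(.pc_cache[[key]])) {
    syn <- place_cue_synapses(neuron, arena)
    .pc_cache[[key]] <- calibrate_baseline_weights(neuron, syn, seed = seed,
                                                   dendritic_threshold = thr)
  }
  .pc_cache[[key]]
}

#' Export the final session weights
#'
#' @param session a `pc_session`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
freeze_and_export_weights <- function(session, path) {
  write_weights_csv(
    session$weights |>
      dplyr::select("synapse_id", "dendrite_id", "g0_peak_uS",
                    "g_peak_max_uS", "A_uS", "g_peak_uS"),
    path, config_hash = rlang::hash(session$config))
}

#' @export
print.pc_session <- function(x, ...) {
  cat("<pc_session> mode:", x$config$mode, "|", x$config$duration_s, "s\n")
  cat("  somatic spikes:", nrow(x$somatic_spikes),
      "| plateau onsets:", length(x$plateau_onsets), "\n")
  pot <- sum(x$weights$g_peak_uS > 1.01 * x$weights$g0_peak_uS)
  cat("  potentiated synapses (>1% above baseline):", pot, "of",
      nrow(x$weights), "\n")
  invisible(x)
}
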