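# Forward-propagating dendritic plateau potential, emulated by four 200 ms
# current steps at apical trunk locations activated sequentially every 500 ms,
# most distal electrode first.

#' Plateau protocol schedule
#'
#' @param neuron a `ca1_neuron`; electrodes default to the midpoints of its
#'   trunk sections, ordered distal first.
#' @param electrodes character vector of 4 trunk compartment ids, strictly
#'   decreasing in path distance to the soma.
#' @param t_start onset of the first (most distal) step, ms.
#' @param step_duration ms.
#' @param inter_onset_interval ms between consecutive electrode onsets.
#' @param amplitude nA injected per electrode, or `"auto"` to calibrate with
#'   [calibrate_plateau_amplitude()] at session setup.
#' @return a `plateau_protocol` object with a `schedule` tibble (columns
#'   `electrode_id`, `onset_ms`, `duration_ms`, `amplitude_nA`).
#' @export
plateau_protocol <- function(neuron, electrodes = NULL, t_start = 0,
                             step_duration = 200, inter_onset_interval = 500,
                             amplitude = "auto") {
  comps <- neuron$compartments
  if (is.null(electrodes)) {
    trunk <- comps |>
      dplyr::filter(.data$region == "trunk") |>
      dplyr::arrange(dplyr::desc(.data$path_distance_to_soma))
    electrodes <- trunk$id[round(seq(1, nrow(trunk), length.out = 4))]
  }
  if (length(electrodes) != 4) abort("the plateau protocol uses 4 electrodes")
  d <- comps$path_distance_to_soma[match(electrodes, comps$id)]
  if (anyNA(d)) abort("unknown electrode compartment id")
  if (any(diff(d) >= 0)) {
    abort("electrodes must be ordered strictly distal to proximal")
  }
  amp <- if (identical(amplitude, "auto")) NA_real_ else amplitude
  structure(list(
    schedule = tibble::tibble(
      electrode_id = electrodes,
      onset_ms = t_start + (0:3) * inter_onset_interval,
      duration_ms = step_duration,
      amplitude_nA = rep_len(amp, 4)),
    t_start = t_start,
    step_duration = step_duration,
    inter_onset_interval = inter_onset_interval),
    class = "plateau_protocol")
}

#' Shift a protocol to a new start time
#' @param protocol a `plateau_protocol`.
#' @param t_start new onset of the first step, ms.
#' @return the shifted protocol.
#' @export
shift_protocol <- function(protocol, t_start) {
  protocol$schedule$onset_ms <-
    t_start + (0:3) * protocol$inter_onset_interval
  protocol$t_start <- t_start
  protocol
}

#' Injected plateau current at one compartment and time
#'
#' @param protocol a `plateau_protocol` (amplitude must be resolved).
#' @param compartment_id compartment id.
#' @param t time, ms (vectorized).
#' @return current, nA: the electrode amplitude while `t` lies in
#'   `[onset, onset + duration)` of that electrode's epoch, else 0.
#' @export
injected_current <- function(protocol, compartment_id, t) {
  s <- protocol$schedule
  k <- match(compartment_id, s$electrode_id)
  if (is.na(k)) return(rep(0, length(t)))
  ifelse(t >= s$onset_ms[k] & t < s$onset_ms[k] + s$duration_ms[k],
         s$amplitude_nA[k], 0)
}

# engine stimulus rows for one epoch (or all): the epoch's total current is
# distributed uniformly over the trunk compartments of the electrode's
# section, mimicking the spatially extended depolarizing wave the current
# steps stand in for; a point injection in a thin trunk cannot.
protocol_stim <- function(neuron, protocol, epochs = 1:4) {
  s <- protocol$schedule
  if (anyNA(s$amplitude_nA[epochs])) abort("protocol amplitude not calibrated")
  comps <- neuron$compartments
  rows <- lapply(epochs, function(k) {
    sec <- comps$section[match(s$electrode_id[k], comps$id)]
    ids <- comps$id[comps$region == "trunk" & comps$section == sec]
    cbind(comp_index0(neuron, ids), s$onset_ms[k], s$duration_ms[k],
          s$amplitude_nA[k] / length(ids))
  })
  do.call(rbind, rows)
}

#' Calibrate the plateau injection amplitudes
#'
#' Calibrates each electrode's injection independently on a geometric grid:
#' the smallest amplitude such that, during that electrode's epoch, (i) the
#' electrode's trunk compartment exceeds the dendritic spike threshold and
#' (ii) every oblique dendrite assigned to that electrode (each oblique is
#' assigned to the electrode nearest in path distance) is depolarized at
#' least `target_depol` above rest. Per-electrode amplitudes compensate for
#' the position-dependent input impedance of the trunk, so all obliques
#' receive a comparable plateau. The search is deterministic; results are
#' cached per configuration.
#'
#' @param neuron a `ca1_neuron`.
#' @param protocol a `plateau_protocol` (amplitude may be `"auto"`/NA).
#' @param target_depol mV above rest required in the assigned obliques.
#' @param dendritic_threshold mV (trunk crossing requirement).
#' @param amp_floor,grid_factor,amp_ceiling geometric amplitude grid, nA.
#' @return numeric vector of 4 amplitudes, nA (distal electrode first).
#' @export
calibrate_plateau_amplitude <- function(neuron, protocol, target_depol = 30,
                                        dendritic_threshold = -10,
                                        amp_floor = 0.05, grid_factor = 1.1,
                                        amp_ceiling = 200) {
  key <- rlang::hash(list("plateau", neuron$config, protocol$schedule$electrode_id,
                          protocol$step_duration, protocol$inter_onset_interval,
                          target_depol, dendritic_threshold, amp_floor,
                          grid_factor))
  if (!is.null(.pc_cache[[key]])) return(.pc_cache[[key]])
  s <- protocol$schedule
  comps <- neuron$compartments
  rest <- setNames(neuron$rest$v, comps$id)
  # assign each oblique to the electrode whose trunk section hosts it; if a
  # section has no electrode, fall back to the electrode nearest in distance
  el_sec <- comps$section[match(s$electrode_id, comps$id)]
  el_dist <- comps$path_distance_to_soma[match(s$electrode_id, comps$id)]
  obl <- comps[comps$region == "oblique", ]
  obl_sec <- comps$section[match(obl$parent, comps$id)]
  assigned <- match(obl_sec, el_sec)
  need_fallback <- is.na(assigned)
  if (any(need_fallback)) {
    assigned[need_fallback] <- apply(
      abs(outer(obl$path_distance_to_soma[need_fallback], el_dist, "-")), 1,
      which.min)
  }
  obl_by_el <- split(obl$id, factor(assigned, levels = 1:4))
  probes <- comp_index0(neuron, comps$id)
  amps <- numeric(4)
  for (k in 1:4) {
    amp <- amp_floor
    ok <- FALSE
    p1 <- protocol
    p1$schedule$onset_ms[k] <- 50
    while (amp <= amp_ceiling) {
      p1$schedule$amplitude_nA[k] <- amp
      stim <- protocol_stim(neuron, p1, epochs = k)
      out <- tryCatch(
        engine_call(neuron, 50 + s$duration_ms[k] + 50,
                    dt = neuron$config$integration$dt_max, stim = stim,
                    probes = probes, record_dt = 1),
        error = function(e) NULL)
      if (is.null(out)) break
      v <- out$v
      colnames(v) <- comps$id
      win <- out$time_ms >= 50 & out$time_ms < 50 + s$duration_ms[k]
      good <- max(v[win, s$electrode_id[k]]) >= dendritic_threshold
      obls <- obl_by_el[[k]]
      if (good && length(obls) > 0) {
        depol <- vapply(obls, function(o) max(v[win, o]) - rest[o], 0)
        good <- min(depol) >= target_depol
      }
      if (good) { ok <- TRUE; break }
      amp <- amp * grid_factor
    }
    if (!ok) {
      abort(paste0("plateau amplitude grid exhausted for electrode ", k,
                   " without meeting the calibration targets"))
    }
    amps[k] <- amp
  }
  .pc_cache[[key]] <- amps
  amps
}

#' Mean-voltage-versus-distance propagation profile
#'
#' Bins compartments by path distance and averages the recorded voltage per
#' bin at each probe sample, the standard way to visualize the distal-to-
#' proximal propagation of the plateau.
#'
#' @param voltage matrix of probe voltages (time x compartments, column names
#'   are compartment ids) as returned by [simulate_neuron()] with
#'   `probes = "all"`.
#' @param time_ms probe sample times.
#' @param neuron the `ca1_neuron` the traces came from.
#' @param bin_width um.
#' @param regions compartment regions included (default trunk + oblique +
#'   soma: the apical propagation axis).
#' @return tibble: `time_ms`, `distance_um` (bin center), `mean_mV`.
#' @export
propagation_profile <- function(voltage, time_ms, neuron, bin_width = 50,
                                regions = c("soma", "trunk", "oblique")) {
  comps <- neuron$compartments
  keep <- comps$id[comps$region %in% regions]
  keep <- intersect(colnames(voltage), keep)
  if (length(keep) == 0) abort("no recorded compartments in the requested regions")
  d <- comps$path_distance_to_soma[match(keep, comps$id)]
  bin <- floor(d / bin_width)
  centers <- (unique(sort(bin)) + 0.5) * bin_width
  agg <- vapply(unique(sort(bin)), function(b) {
    rowMeans(voltage[, keep[bin == b], drop = FALSE])
  }, numeric(length(time_ms)))
  nt <- length(time_ms)
  tibble::tibble(
    time_ms = rep(time_ms, times = length(centers)),
    distance_um = rep(centers, each = nt),
    mean_mV = as.vector(agg))
}
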