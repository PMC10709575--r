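# Spike-timing-dependent plasticity: event-driven updates of the plastic
# increment A, with nearest-neighbor pre/post pairing. The effective peak
# conductance is always g_peak = g0_peak + A, bounded in [g0_peak, g_peak_max].

#' STDP parameters
#'
#' Defaults follow the time-compressed pairing rule used throughout the
#' package: a Gaussian depression window centered at `M` with width `V`, and
#' an exponentially decaying soft-bounded potentiation with e-folding `tau`.
#'
#' @param M center of the depression window, ms (negative: post before pre).
#' @param V width of the depression window, ms.
#' @param tau potentiation e-folding time, ms.
#' @param d depression amplitude (dimensionless).
#' @param p potentiation gain (dimensionless).
#' @param g_peak_max maximum peak conductance, uS (per synapse; may be NA
#'   when carried by the synapse table instead).
#' @param dendritic_spike_threshold local threshold defining postsynaptic
#'   (dendritic spike) events, mV.
#' @return an `stdp_params` list.
#' @export
stdp_params <- function(M = -24, V = 6.32, tau = 2, d = 0.3, p = 1,
                        g_peak_max = NA, dendritic_spike_threshold = -10) {
  if (V <= 0 || tau <= 0 || d <= 0) abort("V, tau and d must be positive")
  structure(list(M = M, V = V, tau = tau, d = d, p = p,
                 g_peak_max = g_peak_max,
                 dendritic_spike_threshold = dendritic_spike_threshold),
            class = "stdp_params")
}

#' Depression update (post before pre)
#'
#' `A' = A * (1 - d * G(delta_t))` with the Gaussian window
#' `G(x) = exp(-(x - M)^2 / (2 V^2)) / (V sqrt(2 pi))`; maximal shrinkage at
#' `delta_t = M`.
#'
#' @param A plastic increment, uS (>= 0).
#' @param delta_t `t_post - t_pre`, ms; must be negative.
#' @param params [stdp_params()].
#' @return updated increment `A'` in `[0, A]`.
#' @export
depression_update <- function(A, delta_t, params = stdp_params()) {
  if (any(delta_t >= 0)) abort("depression branch requires t_post - t_pre < 0")
  G <- exp(-(delta_t - params$M)^2 / (2 * params$V^2)) /
    (params$V * sqrt(2 * pi))
  pmax(0, A * (1 - params$d * G))
}

#' Potentiation update (pre before post)
#'
#' Soft-bounded additive increment
#' `A' = A + (g_peak_max - g0 - A) * p * exp(-delta_t / tau)`, clipped to
#' `[0, g_peak_max - g0]` so the effective weight never exceeds `g_peak_max`.
#'
#' @param A plastic increment, uS.
#' @param delta_t `t_post - t_pre`, ms; must be positive.
#' @param g0 baseline peak conductance, uS.
#' @param params [stdp_params()]; `g_peak_max` must be set (or passed).
#' @param g_peak_max overrides `params$g_peak_max`.
#' @return updated increment `A'`.
#' @export
potentiation_update <- function(A, delta_t, g0, params = stdp_params(),
                                g_peak_max = params$g_peak_max) {
  if (any(delta_t <= 0)) abort("potentiation branch requires t_post - t_pre > 0")
  head <- g_peak_max - g0
  A2 <- A + (head - A) * params$p * exp(-delta_t / params$tau)
  pmin(pmax(A2, 0), head)
}

#' Apply an ordered stream of pre/post events to one synapse
#'
#' Reference event processor used for testing the engine's built-in rule:
#' nearest-neighbor pairing, a pre event at `t` pairs with the most recent
#' post (depression branch, `delta < 0`), a post event pairs with the most
#' recent pre (potentiation, `delta > 0`); an event with no partner only
#' updates the history; exact coincidences (`delta == 0`) are dropped.
#'
#' @param events data frame with columns `time_ms` and `type`
#'   (`"pre"`/`"post"`), nondecreasing in time.
#' @param g0 baseline conductance, uS.
#' @param g_peak_max maximum conductance, uS.
#' @param params [stdp_params()].
#' @param A0 initial increment.
#' @return tibble of the weight trajectory: `time_ms`, `type`, `A_uS`,
#'   `g_peak_uS` (one row per event, including unpaired ones).
#' @export
on_spike_events <- function(events, g0, g_peak_max, params = stdp_params(),
                            A0 = 0) {
  if (is.unsorted(events$time_ms)) abort("events must be in nondecreasing time order")
  A <- A0
  last_pre <- NA_real_
  last_post <- NA_real_
  out_A <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    t <- events$time_ms[i]
    if (events$type[i] == "pre") {
      if (!is.na(last_post) && last_post - t < 0) {
        A <- depression_update(A, last_post - t, params)
      }
      last_pre <- t
    } else {
      if (!is.na(last_pre) && t - last_pre > 0) {
        A <- potentiation_update(A, t - last_pre, g0, params,
                                 g_peak_max = g_peak_max)
      }
      last_post <- t
    }
    out_A[i] <- A
  }
  tibble::tibble(time_ms = events$time_ms, type = events$type,
                 A_uS = out_A, g_peak_uS = g0 + out_A)
}

#' Dendritic spike times of a local voltage trace
#'
#' Postsynaptic events for the STDP rule: upward crossings of the local
#' dendritic threshold (default -10 mV), one per excursion.
#'
#' @param local_trace data frame (`time_ms`, `voltage_mV`) or numeric vector.
#' @param params [stdp_params()].
#' @param time_ms sample times when `local_trace` is a bare vector.
#' @return numeric vector of event times, ms.
#' @export
dendritic_spike_times <- function(local_trace, params = stdp_params(),
                                  time_ms = NULL) {
  detect_threshold_crossings(local_trace, params$dendritic_spike_threshold,
                             time_ms = time_ms)
}
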