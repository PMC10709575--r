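# broom-style tabular views and ggplot2 graphics for sessions and rate maps.

#' Tidy a session result
#'
#' @param x a `pc_session`.
#' @param what one of `"spikes"` (somatic spikes with positions),
#'   `"weights"` (final synaptic weights), `"weight_log"` (event-driven
#'   weight trajectory), `"trajectory"`, `"voltage"` (probe traces, long).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pc_session <- function(x, what = c("spikes", "weights", "weight_log",
                                        "trajectory", "voltage"), ...) {
  what <- match.arg(what)
  switch(what,
    spikes = x$somatic_spikes,
    weights = x$weights,
    weight_log = x$weight_log,
    trajectory = x$trajectory,
    voltage = {
      v <- x$probes$voltage
      tibble::as_tibble(as.data.frame(v)) |>
        dplyr::mutate(time_ms = x$probes$time_ms, .before = 1) |>
        tidyr::pivot_longer(-"time_ms", names_to = "compartment_id",
                            values_to = "voltage_mV")
    })
}

#' One-row session summary
#'
#' @param x a `pc_session`.
#' @param ... unused.
#' @return tibble with mode, duration, somatic spike count, mean rate,
#'   potentiated synapse count, plateau onset count, and the fraction of
#'   spikes emitted while a rewarded-object feature was visible.
#' @export
glance.pc_session <- function(x, ...) {
  n_spk <- nrow(x$somatic_spikes)
  tibble::tibble(
    mode = x$config$mode,
    duration_s = x$config$duration_s,
    n_somatic_spikes = n_spk,
    mean_rate_hz = n_spk / x$config$duration_s,
    n_potentiated = sum(x$weights$g_peak_uS > 1.01 * x$weights$g0_peak_uS),
    n_plateau_onsets = length(x$plateau_onsets),
    frac_spikes_cue_visible = if (n_spk > 0 &&
                                  !all(is.na(x$somatic_spikes$rewarded_visible))) {
      mean(x$somatic_spikes$rewarded_visible)
    } else NA_real_)
}

#' @export
tidy.pc_ratemap <- function(x, ...) {
  cx <- bin_centers(x)
  occ <- as.vector(x$occupancy_s)
  cnt <- as.vector(x$spike_counts)
  rate <- as.vector(x$rate_hz)
  tibble::tibble(
    x = rep(cx, times = length(cx)),
    y = rep(cx, each = length(cx)),
    occupancy_s = occ,
    spike_count = cnt,
    rate_hz = rate)
}

#' @export
glance.pc_ratemap <- function(x, ...) {
  r <- x$rate_hz
  tibble::tibble(
    n_bins = nrow(r),
    total_occupancy_s = sum(x$occupancy_s),
    total_spikes = sum(x$spike_counts),
    peak_rate_hz = if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE),
    masked_bins = sum(is.na(r)))
}

#' Plot a rate map
#'
#' @param object a `pc_ratemap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pc_ratemap <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$rate_hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Firing rate map")
}

#' Plot a session: trajectory, spike positions, objects
#'
#' @param object a `pc_session`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pc_session <- function(object, ...) {
  obj <- object$arena$objects
  p <- ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(color = "grey50", linewidth = 0.3) +
    ggplot2::geom_tile(data = obj,
                       ggplot2::aes(.data$x, .data$y, width = .data$width,
                                    height = .data$height),
                       fill = obj$object_id, inherit.aes = FALSE,
                       alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, object$arena$side_length),
                         ylim = c(0, object$arena$side_length)) +
    ggplot2::labs(x = NULL, y = NULL, title = paste("Session:", object$config$mode))
  if (nrow(object$somatic_spikes) > 0) {
    p <- p + ggplot2::geom_point(data = object$somatic_spikes,
                                 color = "red", size = 1)
  }
  p
}

#' Plot the weight trajectories of a session
#'
#' Piecewise-constant effective peak conductance per synapse over time,
#' colored by object.
#'
#' @param session a `pc_session`.
#' @return a ggplot.
#' @export
plot_weight_traces <- function(session) {
  w <- session$weights
  log <- session$weight_log |>
    dplyr::left_join(w |> dplyr::select("synapse_id", "object_id",
                                        "g0_peak_uS"),
                     by = "synapse_id") |>
    dplyr::mutate(g_peak_uS = .data$g0_peak_uS + .data$A_uS)
  start <- w |>
    dplyr::transmute(.data$synapse_id, .data$object_id, time_ms = 0,
                     g_peak_uS = .data$g0_peak_uS)
  end <- w |>
    dplyr::transmute(.data$synapse_id, .data$object_id,
                     time_ms = session$config$duration_s * 1000,
                     g_peak_uS = .data$g_peak_uS)
  dplyr::bind_rows(start, log, end) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_ms / 1000, .data$g_peak_uS,
                                 group = .data$synapse_id,
                                 color = .data$object_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "g_peak (uS)", color = "object")
}
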