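#' Default configuration for the reduced CA1 neuron
#'
#' Builds the nested configuration list consumed by [build_neuron()]. The
#' morphology is a parameterized reduction of a CA1 pyramidal cell: one soma,
#' a short axon, an apical trunk split into `trunk_sections` sections (each
#' discretized into several compartments), `n_oblique` oblique dendrites
#' attached at distinct trunk positions, and a single basal lump standing in
#' for the basal tree. Channel complement: transient Na, delayed-rectifier K,
#' A-type K with proximal/distal activation variants, hyperpolarization-
#' activated mixed-cation current (h), and muscarinic K (soma and axon only).
#' The A-type and h conductances increase linearly with path distance from
#' the soma.
#'
#' All densities and kinetic constants live in the returned list and can be
#' overridden; units are mV, ms, nA, S/cm2 and um throughout.
#'
#' @param n_oblique number of oblique dendrites (>= 14 for the default
#'   cue-coding scenario of 14 cue synapses).
#' @param trunk_sections number of apical trunk sections (>= 4; the plateau
#'   protocol uses one electrode per section).
#' @param dt integration step, ms.
#' @param ... named overrides merged into the top level of the list.
#' @return a list with elements `morphology`, `channels`, `kinetics`,
#'   `synapse`, `stdp`, `integration`.
#' @export
neuron_config <- function(n_oblique = 14, trunk_sections = 4, dt = 0.025, ...) {
  if (n_oblique < 1 || trunk_sections < 4) {
    abort("need n_oblique >= 1 and trunk_sections >= 4")
  }
  cfg <- list(
    morphology = list(
      n_oblique = n_oblique,
      trunk_sections = trunk_sections,
      comps_per_section = max(4L, ceiling((n_oblique + 2) / trunk_sections)),
      trunk_section_length = 100,           # um
      # proximal neck (first neck_comps compartments at neck_diam) attenuates
      # fast somatic transients while passing sustained currents at DC
      trunk_diams = c(3, 3, 2.5, 2),
      neck_comps = 2L,                      # thin proximal neck compartments
      neck_diam = 1.2,
      soma_length = 20, soma_diam = 20,
      axon_comps = 2L, axon_length = 50, axon_diam = 1,
      oblique_length = 100, oblique_diam = 1.0,
      basal_length = 250, basal_diam = 4,
      axial_resistivity = 150,              # ohm cm
      capacitance = 1,                      # uF/cm2
      leak_conductance = 2.5e-5,              # S/cm2
      leak_reversal = -66
    ),
    # one row per distribution; a channel may appear in several rows
    # (e.g. an axonal Na boost). gbar(x) = max(0, gbar_soma + slope * x),
    # applied only in `regions` and only for x in [x_min, x_max).
    channels = tibble::tribble(
      ~channel, ~gbar_at_soma, ~linear_slope, ~regions, ~reversal, ~x_min, ~x_max,
      "Na",     0.060, 0,      list(c("soma", "axon")),                  55, 0, Inf,
      "Na",     0.160, 0,      list("axon"),                             55, 0, Inf,
      "K_DR",   0.030, 0,      list(c("soma", "axon")),                 -77, 0, Inf,
      "K_DR",   0.020, 0,      list(c("trunk", "basal")),               -77, 0, Inf,
      "K_DR",   0.010, 0,      list("oblique"),                         -77, 0, Inf,
      "K_A_proximal", 0.050, 2e-5, list(c("soma", "trunk", "basal")),   -77, 0, 100,
      "K_A_distal",   0.050, 2e-5, list("trunk"),                       -77, 100, Inf,
      "K_A_distal",   0.010, 2e-5, list("oblique"),                     -77, 0, Inf,
      "I_h",    1.0e-4, 1.5e-6, list(c("soma", "trunk", "oblique", "basal")), -30, 0, Inf,
      "K_M",    0.015, 0,      list(c("soma", "axon")),                 -77, 0, Inf
    ),
    kinetics = c(
      na_m_half = -44, na_m_slope = 5.5, na_m_tau = 0.1,
      na_h_half = -45, na_h_slope = -4,
      na_h_tau_half = -45, na_h_tau_slope = 7, na_h_tau_base = 1, na_h_tau_amp = 8,
      kdr_n_half = -20, kdr_n_slope = 7, kdr_n_tau = 2.5,
      ka_a_half = -35, ka_a_slope = 6, ka_a_tau = 0.2, ka_dist_shift = 0,
      ka_b_half = -60, ka_b_slope = -8, ka_b_tau = 80,
      ih_q_half = -82, ih_q_slope = -7, ih_q_tau = 50,
      km_u_half = -30, km_u_slope = 6, km_u_tau = 40,
      e_na = 55, e_k = -77, e_h = -30
    ),
    synapse = list(
      ampa_rise = 0.5, ampa_decay = 1.0,    # ms
      nmda_rise = 5, nmda_decay = 65,       # ms
      reversal = 0,                         # mV
      mg_concentration = 1.0,               # mM
      mg_eta = 1.0, mg_gamma = 0.09,        # sigmoid Mg-block constants
      nmda_to_ampa_ratio = 2.0,
      ampa_saturation = 1.0,                # receptor-pool saturation (0..1):
      nmda_saturation = 1.0,                # overlapping activations cannot
                                            # exceed the single-event level
      g_max_factor = 3,                     # g_peak_max = factor * g0_peak
      calibration_threshold = -22           # mV: local level the baseline
                                            # weight search holds EPSPs below
    ),
    stdp = list(
      M = -24, V = 6.32, tau = 2, d = 0.3, p = 1,
      dendritic_spike_threshold = -10       # mV
    ),
    integration = list(
      dt = dt, dt_max = 0.05,
      soma_spike_threshold = 0              # mV, output spike detection
    )
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_neuron_config(cfg)
  cfg
}

validate_neuron_config <- function(cfg) {
  m <- cfg$morphology
  geo <- c(m$trunk_section_length, m$soma_length, m$soma_diam, m$axon_length,
           m$axon_diam, m$oblique_length, m$oblique_diam, m$basal_length,
           m$basal_diam, m$axial_resistivity, m$capacitance)
  if (any(!is.finite(geo)) || any(geo <= 0)) {
    abort("non-positive or non-finite geometry in morphology config")
  }
  s <- cfg$synapse
  if (s$ampa_rise >= s$ampa_decay) abort("ampa_rise must be < ampa_decay")
  if (any(c(s$ampa_rise, s$ampa_decay, s$nmda_rise, s$nmda_decay) <= 0)) {
    abort("synaptic time constants must be positive")
  }
  if (s$mg_concentration <= 0) abort("mg_concentration must be positive")
  p <- cfg$stdp
  if (p$V <= 0 || p$tau <= 0 || p$d <= 0) abort("invalid STDP parameters")
  if (cfg$integration$dt <= 0 || cfg$integration$dt > cfg$integration$dt_max) {
    abort("dt must be in (0, dt_max]")
  }
  invisible(cfg)
}

# named kinetics vector for the engine: channel kinetics + synapse + stdp
engine_kinetics <- function(cfg) {
  c(cfg$kinetics,
    mg_eta = cfg$synapse$mg_eta, mg_gamma = cfg$synapse$mg_gamma,
    mg_mM = cfg$synapse$mg_concentration,
    ampa_rise = cfg$synapse$ampa_rise, ampa_decay = cfg$synapse$ampa_decay,
    nmda_rise = cfg$synapse$nmda_rise, nmda_decay = cfg$synapse$nmda_decay,
    e_syn = cfg$synapse$reversal,
    stdp_M = cfg$stdp$M, stdp_V = cfg$stdp$V, stdp_tau = cfg$stdp$tau,
    stdp_d = cfg$stdp$d, stdp_p = cfg$stdp$p)
}

#' Read or write a configuration file
#'
#' Configurations are stored as YAML with sections mirroring the list
#' returned by [neuron_config()] (the channel table is stored as a list of
#' rows).
#'
#' @param path file path.
#' @return `read_neuron_config()` returns a config list; `write_neuron_config()`
#'   returns `path` invisibly.
#' @export
read_neuron_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- neuron_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm == "channels") {
      cfg$channels <- dplyr::bind_rows(lapply(raw$channels, function(row) {
        tibble::tibble(channel = row$channel, gbar_at_soma = row$gbar_at_soma,
                       linear_slope = row$linear_slope,
                       regions = list(unlist(row$regions)),
                       reversal = row$reversal,
                       x_min = as.numeric(row$x_min %||% 0),
                       x_max = as.numeric(row$x_max %||% Inf))
      }))
    } else if (nm == "kinetics") {
      kin <- cfg$kinetics
      kin[names(unlist(raw$kinetics))] <- unlist(raw$kinetics)
      cfg$kinetics <- kin
    } else {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    }
  }
  validate_neuron_config(cfg)
  cfg
}

#' @rdname read_neuron_config
#' @param cfg a configuration list from [neuron_config()].
#' @export
write_neuron_config <- function(cfg, path) {
  out <- cfg
  out$channels <- purrr::pmap(cfg$channels, function(...) {
    row <- list(...)
    row$regions <- unlist(row$regions)
    row
  })
  out$kinetics <- as.list(cfg$kinetics)
  yaml::write_yaml(out, path)
  invisible(path)
}
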