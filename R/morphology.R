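#' Build the reduced compartmental CA1 neuron
#'
#' Constructs the compartment tree (soma, axon chain, trunk chain, oblique
#' dendrites, basal lump), computes path distances and per-compartment
#' channel densities, and settles the model to its resting state with a
#' stimulus-free run. Path distance is measured along the neurite from the
#' soma center to the compartment midpoint, so the distance of a child equals
#' the parent's distance plus the parent-to-child (midpoint to midpoint)
#' segment length.
#'
#' @param config a configuration list from [neuron_config()].
#' @param n_cue_synapses number of cue synapses the model must host (one per
#'   oblique dendrite); `n_oblique` below this is rejected.
#' @param settle_ms duration of the resting settle run, ms.
#' @return an object of class `ca1_neuron`: a list with `compartments`
#'   (a tibble), `config`, engine arrays, and the settled resting state.
#' @examples
#' nrn <- build_neuron(neuron_config(), settle_ms = 200)
#' compartments(nrn)
#' @export
build_neuron <- function(config = neuron_config(), n_cue_synapses = 14,
                         settle_ms = 1000) {
  m <- config$morphology
  if (m$n_oblique < n_cue_synapses) {
    abort(paste0("n_oblique = ", m$n_oblique, " cannot host ", n_cue_synapses,
                 " cue synapses (one per oblique dendrite)"))
  }
  n_trunk <- m$trunk_sections * m$comps_per_section
  if (m$n_oblique > n_trunk) {
    abort("more oblique dendrites than trunk compartments to attach them to")
  }
  trunk_diams <- m$trunk_diams %||%
    seq(3, 1.5, length.out = m$trunk_sections)
  comp_len <- m$trunk_section_length / m$comps_per_section

  rows <- list(tibble::tibble(
    id = "soma", region = "soma", parent = NA_character_,
    length = m$soma_length, diameter = m$soma_diam, section = NA_integer_))
  # axon chain off the soma
  for (k in seq_len(m$axon_comps)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = paste0("axon_", k), region = "axon",
      parent = if (k == 1) "soma" else paste0("axon_", k - 1),
      length = m$axon_length, diameter = m$axon_diam, section = NA_integer_)
  }
  # basal lump off the soma
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = "basal", region = "basal", parent = "soma",
    length = m$basal_length, diameter = m$basal_diam, section = NA_integer_)
  # apical trunk chain
  prev <- "soma"
  n_neck <- m$neck_comps %||% 0L
  for (s in seq_len(m$trunk_sections)) {
    for (k in seq_len(m$comps_per_section)) {
      id <- paste0("trunk_", s, "_", k)
      diam <- trunk_diams[s]
      # thin proximal neck: strong attenuation of fast somatic transients
      if (s == 1 && k <= n_neck && !is.null(m$neck_diam)) diam <- m$neck_diam
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = id, region = "trunk", parent = prev,
        length = comp_len, diameter = diam, section = s)
      prev <- id
    }
  }
  comps <- dplyr::bind_rows(rows)
  trunk_ids <- comps$id[comps$region == "trunk"]
  # obliques attached at distinct, evenly spread trunk compartments
  # (beyond the proximal neck, which is a pure coupling cable)
  first_ok <- (m$neck_comps %||% 0L) + 1L
  if (n_trunk - first_ok + 1L < m$n_oblique) first_ok <- 1L
  attach_idx <- unique(round(seq(first_ok, n_trunk, length.out = m$n_oblique)))
  while (length(attach_idx) < m$n_oblique) { # guard against rounding collisions
    attach_idx <- sort(union(attach_idx, setdiff(seq_len(n_trunk), attach_idx)[1]))
  }
  obl <- tibble::tibble(
    id = paste0("oblique_", seq_len(m$n_oblique)), region = "oblique",
    parent = trunk_ids[attach_idx[seq_len(m$n_oblique)]],
    length = m$oblique_length, diameter = m$oblique_diam, section = NA_integer_)
  comps <- dplyr::bind_rows(comps, obl)

  # path distance: soma center = 0; child = parent + (L_parent + L_child) / 2
  dist <- setNames(rep(NA_real_, nrow(comps)), comps$id)
  dist["soma"] <- 0
  for (i in seq_len(nrow(comps))[-1]) {
    p <- comps$parent[i]
    plen <- if (p == "soma") 0 else comps$length[match(p, comps$id)]
    dist[comps$id[i]] <- dist[p] + (plen + comps$length[i]) / 2
  }
  comps$path_distance_to_soma <- unname(dist[comps$id])
  comps$axial_resistivity <- m$axial_resistivity
  comps$specific_capacitance <- m$capacitance
  leak_mult <- rep(1, nrow(comps))
  if (!is.null(m$region_leak_multiplier)) {
    for (rg in names(m$region_leak_multiplier)) {
      leak_mult[comps$region == rg] <- m$region_leak_multiplier[[rg]]
    }
  }
  comps$leak_conductance <- m$leak_conductance * leak_mult
  comps$leak_reversal <- m$leak_reversal

  # engine arrays -----------------------------------------------------------
  area_cm2 <- pi * (comps$diameter * 1e-4) * (comps$length * 1e-4)
  half_res_ohm <- m$axial_resistivity * (comps$length / 2 * 1e-4) /
    (pi * (comps$diameter / 2 * 1e-4)^2)
  parent_idx <- match(comps$parent, comps$id) # NA for soma
  g_axial <- ifelse(is.na(parent_idx), 0,
                    1e6 / (half_res_ohm + half_res_ohm[parent_idx]))

  chan_order <- c("Na", "K_DR", "K_A", "I_h", "K_M")
  gbar <- matrix(0, nrow(comps), 5,
                 dimnames = list(comps$id, chan_order))
  for (r in seq_len(nrow(config$channels))) {
    row <- config$channels[r, ]
    ch <- if (row$channel %in% c("K_A_proximal", "K_A_distal")) "K_A" else row$channel
    x <- comps$path_distance_to_soma
    in_range <- x >= row$x_min & x < row$x_max
    in_region <- comps$region %in% unlist(row$regions)
    dens <- pmax(0, row$gbar_at_soma + row$linear_slope * x)
    gbar[, ch] <- gbar[, ch] + ifelse(in_range & in_region, dens, 0) * area_cm2 * 1e6
  }
  ka_split <- {
    dr <- config$channels[config$channels$channel == "K_A_distal", ]
    if (nrow(dr) > 0) min(dr$x_min) else Inf
  }

  nrn <- structure(list(
    compartments = comps,
    config = config,
    engine = list(
      parent = as.integer(ifelse(is.na(parent_idx), -1L, parent_idx - 1L)),
      c_nF = m$capacitance * area_cm2 * 1e3,
      g_leak_uS = comps$leak_conductance * area_cm2 * 1e6,
      e_leak = rep(m$leak_reversal, nrow(comps)),
      g_axial_uS = g_axial,
      gbar_uS = gbar,
      ka_distal = as.integer(comps$path_distance_to_soma >= ka_split &
                               comps$region %in% c("trunk", "oblique")),
      kinetics = engine_kinetics(config)
    ),
    oblique_ids = obl$id,
    trunk_sections = m$trunk_sections,
    rest = NULL
  ), class = "ca1_neuron")

  # settle to steady state and store as the resting initial condition
  if (settle_ms > 0) {
    out <- engine_call(nrn, duration_ms = settle_ms, probes = integer(0),
                       record_stride = 0L)
    nrn$rest <- list(v = out$v_final, gating = out$gating_final)
  }
  nrn
}

#' Compartment table of a neuron
#'
#' @param neuron a `ca1_neuron`.
#' @return tibble of compartments with geometry and path distances.
#' @export
compartments <- function(neuron) {
  stopifnot(inherits(neuron, "ca1_neuron"))
  neuron$compartments
}

#' @export
print.ca1_neuron <- function(x, ...) {
  tab <- table(x$compartments$region)
  cat("<ca1_neuron> ", nrow(x$compartments), " compartments (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  if (!is.null(x$rest)) {
    cat("  resting potential: ",
        sprintf("%.1f", mean(x$rest$v)), " mV (mean over compartments)\n", sep = "")
  }
  invisible(x)
}

#' Channel conductance density at a path distance
#'
#' Evaluates `max(0, gbar_at_soma + linear_slope * x)` for one distribution
#' row, returning 0 when `region` is outside the distribution's region mask
#' or `x` outside its distance window.
#'
#' @param distribution one row of the channel table (see [neuron_config()]).
#' @param x path distance from the soma, um (>= 0).
#' @param region compartment region the query refers to.
#' @return conductance density, S/cm2.
#' @export
channel_density_at <- function(distribution, x, region) {
  if (any(x < 0)) abort("path distance must be non-negative")
  stopifnot(nrow(distribution) == 1)
  in_mask <- region %in% unlist(distribution$regions)
  in_range <- x >= distribution$x_min & x < distribution$x_max
  ifelse(in_mask & in_range,
         pmax(0, distribution$gbar_at_soma + distribution$linear_slope * x), 0)
}
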