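Package: placecellr
Title: Simulating Hippocampal Place-Cell Formation in a Compartmental CA1 Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator of place-cell formation in a reduced
    compartmental CA1 pyramidal neuron. Cue-coding AMPA+NMDA synapses on
    oblique dendrites, driven by Poisson presynaptic trains whose rates depend
    on what a virtual agent sees while exploring a square arena, are
    selectively potentiated by a spike-timing-dependent plasticity rule when a
    forward-propagating dendritic plateau potential (four sequential apical
    trunk current steps) coincides with cue viewing. Includes per-dendrite
    baseline-weight calibration, plateau amplitude calibration, session
    orchestration (control, learning, recall, arena rotation, remapping), and
    place-field rate-map analysis with ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
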