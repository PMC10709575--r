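# Shared fixtures, built once per test run and cached. Everything is
# generated in code; the calibrations are deterministic given their seeds.

.fx <- new.env(parent = emptyenv())

fx_neuron <- function() {
  if (is.null(.fx$neuron)) .fx$neuron <- build_neuron()
  .fx$neuron
}

fx_arena <- function() {
  if (is.null(.fx$arena)) .fx$arena <- arena()
  .fx$arena
}

fx_weights <- function() {
  if (is.null(.fx$weights)) {
    .fx$weights <- placecellr:::calibrated_weights(fx_neuron(), fx_arena(),
                                                   seed = 42)
  }
  .fx$weights
}

fx_protocol <- function() {
  if (is.null(.fx$protocol)) {
    p <- plateau_protocol(fx_neuron())
    p$schedule$amplitude_nA <- calibrate_plateau_amplitude(fx_neuron(), p)
    .fx$protocol <- p
  }
  .fx$protocol
}

# canonical sessions at the default seed triple
fx_control <- function() {
  if (is.null(.fx$control)) {
    .fx$control <- run_session(fx_neuron(), fx_arena(),
                               session_config("control_no_plateau",
                                              rewarded_object = "red"),
                               weights = fx_weights())
  }
  .fx$control
}

fx_learning <- function() {
  if (is.null(.fx$learning)) {
    .fx$learning <- run_session(fx_neuron(), fx_arena(),
                                session_config("learning_with_plateau",
                                               rewarded_object = "red"),
                                weights = fx_weights())
  }
  .fx$learning
}

fx_recall <- function() {
  if (is.null(.fx$recall)) {
    .fx$recall <- run_session(fx_neuron(), fx_arena(),
                              session_config("recall", rewarded_object = "red",
                                             seeds = list(trajectory = 33,
                                                          synaptic = 44,
                                                          calibration = 42)),
                              weights = fx_weights(),
                              A0 = fx_learning()$weights$A_uS)
  }
  .fx$recall
}
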