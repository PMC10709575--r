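# placecellr

`placecellr` simulates how a hippocampal CA1 pyramidal neuron becomes a
**place cell**. It is a self-contained co-simulation of

- a reduced compartmental CA1 neuron (soma, axon, four-section apical trunk,
  14 oblique dendrites, basal lump) with Hodgkin-Huxley-style channels
  (transient Na, delayed-rectifier K, A-type K with a distance gradient,
  h-current, muscarinic K),
- one AMPA+NMDA cue synapse per oblique dendrite, with voltage-dependent
  Mg²⁺ block and per-dendrite baseline weights calibrated to sit just below
  the local dendritic spike threshold at background activity,
- a spike-timing-dependent plasticity (STDP) rule driven by local dendritic
  spikes (upward crossings of −10 mV),
- a forward-propagating dendritic **plateau potential**, emulated by four
  200 ms current steps along the apical trunk activated every 500 ms from
  the most distal location inward, and
- a virtual agent exploring a square arena with bar-shaped objects whose
  features drive the cue synapses: features in the 90° visual field fire at
  80 Hz (gamma), everything else at 3 Hz (theta).

When the agent views the rewarded object while the plateau sweeps the trunk,
the co-active cue synapses cross the dendritic spike threshold and the STDP
rule potentiates them — and only them. Afterwards the neuron fires
preferentially where that cue is in view: a place field.

## The plasticity rule

The effective peak conductance of each synapse is `g_peak(t) = g0_peak + A(t)`,
with `A` updated at every pre- or postsynaptic (local dendritic) spike:

- depression, for `Δt = t_post − t_pre < 0`:
  `A ← A · (1 − d · exp(−(Δt − M)² / 2V²) / (V√(2π)))`
- potentiation, for `Δt > 0`:
  `A ← A + (g_peak_max − g0_peak − A) · p · exp(−Δt/τ)`

with `M = −24 ms`, `V = 6.32 ms`, `τ = 2 ms`, `d = 0.3`, `p = 1`, and `A`
clipped to `[0, g_peak_max − g0_peak]`.

## A worked example

```r
library(placecellr)

neuron <- build_neuron()      # builds and settles the reduced CA1 neuron
ar     <- arena()             # 1 x 1 arena with a red and a blue bar

# learning: plateau triggered when the red bar comes into view
learn <- run_session(neuron, ar,
                     session_config("learning_with_plateau",
                                    rewarded_object = "red"))
glance(learn)
#>   mode                  duration_s n_somatic_spikes ... n_potentiated
#> 1 learning_with_plateau        120               20 ...             7

# every potentiated synapse codes for the red bar
dplyr::count(tidy(learn, "weights"),
             object_id, potentiated = g_peak_uS > 1.01 * g0_peak_uS)
#>   object_id potentiated n
#> 1 blue      FALSE       7
#> 2 red       TRUE        7

# recall: weights stay free; the neuron now fires where the red bar is seen
rec <- run_session(neuron, ar,
                   session_config("recall", rewarded_object = "red",
                                  seeds = list(trajectory = 33, synaptic = 44,
                                               calibration = 42)),
                   A0 = learn$weights$A_uS)
mean(rec$somatic_spikes$rewarded_visible)   # 1.0: all spikes during viewing
autoplot(rate_map(rec, n_bins = 10))        # the place-field rate map
```

A matched control session (`"control_no_plateau"`, same seeds) produces zero
somatic spikes during cue viewing and leaves every weight within 1% of its
baseline: the plateau is what gates learning.

Command-line front ends live in `inst/scripts/` (`run_session.R`,
`analyze_session.R`); the default configuration is exported at
`inst/extdata/default_config.yaml` and can be edited and passed back via
`--config`.

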