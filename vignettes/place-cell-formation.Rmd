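---
title: "Modeling place-cell formation in a compartmental CA1 neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling place-cell formation in a compartmental CA1 neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`placecellr` is a cellular-level simulator of place-cell formation: a single
CA1 pyramidal neuron, embedded in a virtual spatial environment, acquires a
place field through the interaction of two spatially segregated excitatory
inputs — cue-coding synapses on its oblique dendrites (the CA3 / Schaffer
collateral pathway) and a distally initiated, forward-propagating plateau
potential standing in for entorhinal drive. This vignette explains the model,
its assumptions, the parameters that matter, and the choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The model in one paragraph

A virtual agent performs a random walk in a square arena containing two
bar-shaped objects, each decomposed into seven features. Every feature maps
to one synapse on one oblique dendrite. Features inside the agent's 90°
visual field drive their synapse at 80 Hz (gamma); everything else ticks
along at 3 Hz (theta). Each synapse's baseline weight is calibrated so that
background activation stays just below the local dendritic spike threshold,
so ordinary exploration produces no dendritic spikes, no somatic output, and
no plasticity. When the rewarded object comes into view, a plateau protocol —
four 200 ms current steps applied along the apical trunk every 500 ms, most
distal first — depolarizes the obliques. On that pedestal, the sustained
NMDA conductance of the 80 Hz cue-driven synapses (and only those) pushes
their dendrites across the −10 mV dendritic spike threshold; the STDP rule
pairs these local spikes with the immediately preceding presynaptic spikes
and potentiates exactly the rewarded pathway. With the weights raised
(up to `g_max_factor` = 3x baseline), viewing the cue later drives the soma:
the neuron has become a place cell whose field is the region from which the
cue is resolvable.

## The neuron

The morphology is a parameterized reduction (34 compartments by default):
soma, a two-compartment axon, an apical trunk of four 100 µm sections, 14
oblique dendrites attached at distinct trunk positions, and one basal lump.
Two design features of the reduction carry real weight:

- **A thin proximal "neck"** (the first two trunk compartments at 1.2 µm).
  Its high axial resistance low-pass filters the soma-dendrite coupling:
  fast transients — somatic action potentials backpropagating into the tree,
  coincident EPSP volleys — are attenuated, while sustained currents (the
  plateau, the aggregate drive of potentiated synapses during cue viewing)
  pass at DC. This keeps the control condition somatically silent and keeps
  backpropagating spikes from creating spurious dendritic-spike events,
  while still letting the formed place cell fire during recall.
- **Passive dendrites, excitable perisomatic region.** Na and the
  delayed-rectifier dominate in the soma/axon; the trunk and obliques carry
  K_DR, A-type K (with a positive distance gradient, strongest role:
  damping transients in the trunk), and h-current (also with a positive
  gradient). Dendritic spikes in this model are therefore NMDA/AMPA
  threshold crossings rather than local Na spikes. We found a
  calibration-to-threshold loop combined with regenerative dendritic Na to
  be structurally fragile: any mechanism that raises a dendrite toward
  threshold recruits the Na nonlinearity completely, so single background
  EPSPs during the plateau ignite full spikes and destroy input
  specificity. With passive dendrites the crossing is graded and the
  rate-selectivity of the NMDA pool decides.

Channel kinetics are canonical sigmoidal steady-state/time-constant
formulations with all constants in the configuration
(`neuron_config()$kinetics`); densities are configuration defaults tuned so
that the behavioral contrasts hold (resting potential ≈ −66 mV, somatic
rheobase ≈ 0.2–0.3 nA, repetitive firing, stable rest). Integration is
backward-Euler for the cable tree (a Hines solve) with exponential-Euler
gating, dt = 0.025 ms by default and 0.05 ms in the standard sessions; both
are well inside the convergence tolerance checked by the test suite.

## The synapse

Each cue synapse is one AMPA+NMDA pair representing the synchronous
activation of a group of real synapses. AMPA: double-exponential, 0.5/1 ms.
NMDA: double-exponential, 5/65 ms, multiplied by the sigmoid Mg block
`1/(1 + η[Mg]e^{−γV})` with η = 1 mM⁻¹, γ = 0.09 mV⁻¹ at 1 mM Mg²⁺; the
reversal is 0 mV for both. Two choices deserve comment:

- **Receptor-pool saturation** (`ampa_saturation`, `nmda_saturation` = 1):
  an incoming spike tops the synaptic state up to the single-event level
  instead of adding to it. Because each model synapse lumps a whole group of
  receptors, a second synchronous volley arriving within the decay of the
  first cannot recruit more conductance than the pool holds. This makes the
  response to an 80 Hz train a *sustained* conductance at the single-event
  amplitude rather than a growing one — the decisive property that lets a
  synapse calibrated "just below threshold" at 3 Hz remain subthreshold at
  80 Hz (the control condition), while still carrying a rate signal: at
  80 Hz the NMDA conductance is continuously present, at 3 Hz it is an
  isolated 65 ms pulse.
- **A steeper-than-usual Mg curve** (γ = 0.09 mV⁻¹). The selectivity margin
  of the learning rule is the ratio of the NMDA current at the
  plateau-depolarized dendritic baseline to that near rest; the steeper
  curve buys roughly a factor two of margin. The qualitative contract
  (monotone in V, → 0 hyperpolarized, → 1 depolarized) is unchanged.

**Baseline calibration.** For each dendrite separately, the largest weight on
a geometric grid (factor 1.25) is selected such that a 10 s, fixed-seed,
3 Hz activation of that synapse alone never crosses the *calibration
threshold* of −22 mV. Calibrating against −22 mV rather than the −10 mV
spike threshold itself gives every dendrite a uniform ≈ 10 mV safety margin;
with the grid's 25% quantization, calibrating to the exact threshold leaves
some dendrite arbitrarily close to it, and any depolarizing perturbation — a
plateau, a neighbor's potentiated synapse — then flips it. "Just below
threshold" is implemented conservatively for this reason. Distal dendrites
end up with larger local conductances (their input impedance is lower toward
the trunk sink), which keeps single-synapse somatic EPSPs within the same
order of magnitude across the tree.

## The plateau protocol

Four electrodes along the trunk (one per section, distal first) inject
200 ms current steps with onsets 500 ms apart — a 1.7 s sweep with 300 ms
gaps, emulating the forward-propagating calcium wave. Amplitudes are
calibrated per electrode: the smallest grid value such that, during its
epoch, the electrode's trunk compartment exceeds −10 mV and every oblique
assigned to that electrode is depolarized at least `target_depol` = 32 mV
above rest. Per-electrode calibration compensates the position-dependent
trunk impedance so all obliques receive a comparable pedestal. The injected
current is distributed uniformly over the electrode's trunk section — a
point source in a thin cable cannot depolarize its neighborhood without
locally diverging, and the current step is in any case a surrogate for a
spatially extended wave. In environment-coupled sessions the protocol starts
when the rewarded object *enters* the visual field (a rising edge with at
least six of seven features resolvable), with a 60 s refractory lockout, and
stops re-arming once all of the rewarded object's synapses are potentiated —
the reward signal stops re-engaging once the association is consolidated.
(`min_visible_features = 1`, `trigger_refractory_s = Inf` restore a
literal once-per-session, any-feature trigger.)

## The plasticity rule

Weights update at every pre- or postsynaptic event, where "post" means an
upward crossing of −10 mV in the synapse's own dendrite (somatic spikes play
no direct role). Pairing is nearest-neighbor. Depression uses a Gaussian
window centered at M = −24 ms with width V = 6.32 ms and amplitude d = 0.3;
potentiation is an additive soft-bounded increment with e-folding τ = 2 ms
and gain p = 1, and `A` is clipped to `[0, g_peak_max − g0_peak]` after every
update. Two interpretation points: the depression exponent is read as the
normalized Gaussian `exp(−(Δt−M)²/2V²)/(V√2π)`; and the potentiation
recurrence is implemented additively — a multiplicative form
`A(t+dt) = A(t)·(…)` pins `A` at zero forever from the standard initial
condition `A(0) = 0`, so it cannot express potentiation at all. The τ = 2 ms
window also explains a useful property: dendritic crossings that *lag* their
presynaptic spike by tens of milliseconds (slow NMDA-driven events)
potentiate negligibly, so only crossings ignited promptly by a presynaptic
event — which during the plateau happen essentially only on 80 Hz inputs —
move weights appreciably.

## The environment

Square arena (side 1), two 0.4 × 0.05 bars in opposite quadrants, seven
features per object spaced along the bar. The agent moves at 0.08 units/s
with Gaussian heading increments (SD 4° per 100 ms step) and reflecting
walls; these defaults make cue-viewing bouts of roughly 2–3 s, matching the
1.7 s plateau sweep. Vision: 90° field of view; full resolution out to a
foveal range of 0.35, then a linear falloff to zero at 1.2, with an object's
features resolvable in a fixed order (`ceiling(decay(r) · 7)` of them at
object distance r). A strictly linear falloff made the last-ranked feature
resolvable only within 0.17 units, structurally capping learning at six of
seven synapses; the foveal plateau removes that cap while keeping the
firing zone bounded. Presynaptic trains are inhomogeneous Poisson processes,
piecewise-constant at the 100 ms environment step, fully reproducible from
the session's seed triple (trajectory / synaptic / calibration).

## Sessions and problem sizes

Scaled-down defaults keep everything desk-sized: 60 s control, 120 s
learning, 300 s recall (the corresponding in-vivo protocols run tens of
minutes), at dt = 0.05 ms, ~34 compartments, 14 synapses. A 120 s learning
session simulates in seconds; the full calibration (14 dendrites × a
geometric weight search) takes under a minute and is cached per
configuration. Determinism is exact: identical seed triples give
bit-identical spike times and weight trajectories.

## What the generator does and does not emulate

The synthetic environment reproduces the structure of the paradigm — cue
rates set by gaze, a single reward-gated plateau pathway, theta/gamma rate
coding — but not real visual processing, theta-phase timing, inhibition, or
behavioral biases of real rodents (wall-following in the random walk is an
artifact, not thigmotaxis). Consequences seen in the analyses: the formed
place field is the region *from which the cue is resolvable*, convolved with
the walk's dwell pattern, rather than a compact blob on the object. The
rotation experiment (the field follows a 90° arena rotation) behaves as
expected because the whole viewshed rotates; the two-object remapping
experiment, by contrast, separates field centroids only weakly at these
session lengths, because both viewsheds overlap the high-dwell interior —
this is recorded as a known limitation rather than hidden by a looser test.

## Numerical choices and degenerate inputs

Voltage integration is unconditionally stable (implicit cable solve); NaN or
out-of-range voltages abort with the offending compartment and time. Gating
variables are table-driven and clamped to [0, 1]. Spike detection uses a
single-excursion rule (a new event requires falling back below threshold).
Exact pre/post coincidences (Δt = 0) are dropped — neither STDP branch is
defined there. Ties between a presynaptic delivery and a dendritic crossing
within one dt resolve pre-before-post. The dt-convergence check runs on a
subthreshold stimulus: with spikes present, sub-millisecond timing jitter
between step sizes makes a pointwise RMS meaningless.

## Known limitations

- Place fields are viewshed-shaped (see above); remapping separation is
  weak at scaled session lengths.
- The potentiated/not-potentiated count after a single 120 s learning
  session varies with the seed (typically 5–9 potentiated synapses,
  median 7): a single short viewing bout may span only part of the plateau
  sweep.
- No inhibition, no calcium dynamics, no receptor desensitization or release
  stochasticity; one synapse per dendrite; somatic EPSP equalization across
  dendrites holds only to within a factor of a few.
- Channel kinetics and densities are behavioral-level calibrations, not fits
  to voltage-clamp data; the model's claims are about the logic of
  plateau-gated plasticity, not about trace-level biophysics.
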