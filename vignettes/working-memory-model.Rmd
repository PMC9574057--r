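---
title: "A spiking working-memory network sustained by synaptic facilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking working-memory network sustained by synaptic facilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmnet)
```

## The model

`wmnet` simulates a recurrent cortical-style network in which working
memory is held *synaptically* rather than by persistent spiking: loading an
item transiently facilitates the synapses of the selective neuron
population that encodes it, and that facilitation — not sustained firing —
carries the memory across the delay period.

### Neurons

All `r 8000` excitatory and `r 2000` inhibitory cells are leaky
integrate-and-fire neurons with exponential postsynaptic currents,

$$\tau_m \dot V_j = -V_j + R_m\,(I^{exc}_j + I^{inh}_j + I^{ext}_j),
\qquad
\tau_{syn} \dot I^{exc/inh}_j = -I^{exc/inh}_j + \text{spike jumps},$$

with the membrane expressed relative to rest (no explicit leak reversal),
a fixed threshold $V_{th}$, reset to $V_{reset}$, and an absolute
refractory period during which the membrane is clamped while synaptic
currents keep evolving. Because the sub-threshold system is linear, each
time step of width $dt$ is advanced *exactly* by precomputed propagator
coefficients (`lif_propagator()`); the only discretization left is the
threshold check at step boundaries. The default grid, $dt = 0.05$ ms, was
verified to be in the regime where halving the step does not change
population behaviour appreciably.

The external drive is piecewise-constant Gaussian noise: each targeted
neuron receives an independent current $\mu + \sigma G_k$ redrawn every 1
ms. Per-neuron delay offsets of the drive are realized as independent
noise streams per neuron, which is statistically equivalent to literal
time shifts of a shared stream and simpler to reproduce exactly from a
seed.

Synaptic efficacies $J$ are stated in millivolts of *peak* postsynaptic
potential. A delivered spike enters the target's synaptic current as a
jump $\alpha J / \tau_{syn}$, where `alpha_factor()` solves the peak
condition analytically: the PSP maximum, reached at
$t_{peak} = \frac{\tau_m \tau_{syn}}{\tau_m - \tau_{syn}}
\ln(\tau_m/\tau_{syn})$, equals exactly $J$ mV. This is the natural
convention when porting delta-synapse efficacies to exponential currents,
but it is worth noting that it inflates the *time-integral* of each PSP by
$\approx 36\%$ relative to a delta synapse of the same $J$ (for
$\tau_m = 15$, $\tau_{syn} = 2$ ms) — a point that matters for parameter
choices below.

### Short-term plasticity

Every excitatory-to-excitatory synapse carries Tsodyks–Markram dynamics:
utilization $u$ (facilitation; residual presynaptic calcium) decays to a
baseline $U$ with time constant $\tau_f$, and resources $x$ (available
neurotransmitter) recover to 1 with $\tau_d$. A presynaptic spike at $t$
first facilitates, $u^+ = u^- + U(1-u^-)$, then releases $u^+ x^-$, and
the delivered efficacy is

$$J_{eff} = J\,u(t^+)\,x(t^-),$$

the `post_u` ordering in which the spike's own calcium influx contributes
to its release. The alternative `pre_u` ordering ($J\,u^-x^-$) is
available as a run flag; for identical trains it never releases more, the
ratio being $u^+/u^- \ge 1$, with the difference largest at low rates.

The synapse state is updated *event-wise*: nothing is integrated per time
step; at each presynaptic spike the closed-form exponential decay since
the previous spike is applied, followed by the jump (`stp_decay()`,
`stp_spike_update()`). The defaults $\tau_d = 200$ ms, $\tau_f = 1500$ ms
put all plastic synapses deep in the facilitation-dominated regime.
$U = 0.19$ is derived by inverting the analytic limit-cycle period (below)
against its published value of about 445 ms.

### Network structure

Five selective populations of 800 excitatory neurons (disjoint by default;
an overlap mode draws them independently at random) encode one item each;
the remaining 4000 excitatory cells are non-selective. Intra-population
synapses carry a potentiated efficacy $J_p$, emulating prior long-term
Hebbian learning; all other excitatory pairs carry the baseline $J_b$,
except 10% of the non-selective pairs which are potentiated as well.
Every neuron receives a fixed in-degree from each source class
(`round(c N_E)` excitatory, `round(c N_I)` inhibitory sources, drawn with
replacement so multapses are possible, each with its own state and a
uniform 0.1–1.0 ms delay). Inhibitory connectivity is non-specific and
static; it implements the global competition through which exactly one
selective population can burst at a time (winner-take-all).

## Memory regimes and calibration

Three levels of the mean excitatory background current select the
operating regime. All three are found by the package's own calibration
(`calibrate_background()` plus regime scans), because absolute current
levels are meaningful only relative to the realized network gain:

* **Regime B** (`mu_bg_E_B`): the *bistable* regime. Spontaneous activity
  is calibrated to about 0.7 Hz; after a 350 ms item-loading current into
  one population, the network autonomously emits periodic population
  spikes (PS) of that population — brief synchronized volleys that refresh
  $u$ and deplete $x$, recurring on a timescale set by the depression
  recovery, a few hundred ms. Lowering the background back to the regime-A
  level terminates the activity.
* **Regime A** (`mu_bg_E`): background low enough that the limit cycle
  cannot self-sustain. After loading, the network returns to its baseline
  and the item survives only in the elevated $u$ of the loaded
  population's synapses (activity-silent memory); a later nonspecific
  readout pulse to *all* excitatory neurons reignites a population spike
  only in the loaded population.
* **Regime C** (`mu_bg_E_C`): further increased background; the loaded
  population settles into asynchronous elevated firing several Hz above
  baseline.

Each level is anchored to its own published observable. The inhibitory
background `mu_bg_I` is fixed first, since it sets the gain of the
feedback loop the other levels are measured against. A spontaneous
reference level (`mu_bg_E_spont`) is bisected so the background-only
network sits at 0.7 Hz. The regime-B level is then calibrated against the
~300 ms inter-reactivation interval of a single loaded item (it lies
slightly above the 0.7 Hz point; its own pre-load baseline is ~0.8 Hz).
The regime-A level is chosen below the autonomous-reactivation threshold
and the regime-C level above the asynchronous transition, each verified
by a loading probe. The reproduction script re-bisects the spontaneous
level for the network realization at hand and shifts all regime levels by
the same correction.

### A deliberate departure: the potentiated efficacy

With the reference-family weight set ($J_p = 0.45$ mV and peak-matched
$\alpha$), the facilitated recurrent loop turned out to be supercritical
already at baseline utilization: selective populations ignited
spontaneously into persistent activity before the network could reach a
0.7 Hz homogeneous state, for every combination of background levels and
noise widths we probed. This is a direct consequence of the 36% PSP-integral
inflation noted above: peak-matching preserves unitary PSP *amplitudes*
but strengthens the *mean* recurrent drive relative to the delta-synapse
model the weights come from. We therefore calibrated $J_p$ down to
0.305 mV (leaving all other weights at reference values), the largest
value at which the spontaneous state is stable and homogeneous at 0.7 Hz
while loading still switches the network into the
synchronous-reactivation limit cycle, and widened the background noise to
$\sigma = 2$ mV, which balances the competition between concurrently held
items. Both values are package calibrations, tagged as such in
`wm_defaults()$provenance`, and overridable in the configuration.

This compromise has a measurable cost at high memory load. Population
spikes at the calibrated point recruit roughly a third of the population
for about one spike each (the available-resource average drops from
$\approx 0.7$ to $\approx 0.5$ per volley), because full recruitment
within the few milliseconds before feedback inhibition closes the volley
would require roughly twice the facilitated coupling $J_p u x$ — which the
spontaneous-stability ceiling forbids. Shallow volleys leave part of a
population's synapses unrefreshed, so while one item reactivates
indefinitely and two items alternate cleanly, a third item is held only
intermittently: all three populations keep emitting population spikes,
but one or two of them typically violate the strict no-gap criterion of
`count_held_items()`, and the pooled inter-PS spacing of the held
populations settles several-fold above the ~160 ms that three tightly
interleaved items would give (near 250–330 ms when all three stay
engaged, and at a single population's own ~350–550 ms cycle when only
one remains held). The package reports these quantities exactly as measured; the
capacity growth with $\tau_f$ remains visible analytically through
[tmax_estimate()] but is not reproduced by the simulated network at this
operating point.

## Analysis machinery

* `population_rate()` bins a population's raster into Hz per neuron.
* `detect_population_spikes()` defines a PS operationally — the source
  literature never formalizes it — as a contiguous excursion above
  `threshold_factor` (default 10) times the baseline-window mean rate
  (5 ms bins, absolute floor 10 Hz for silent baselines), with excursions
  closer than 50 ms merged and the peak bin reported. On constructed
  volley fixtures with contrast $\ge 10$ the detector is exact.
* `firing_rate_difference()` implements the per-neuron spike-count rate
  difference $\Delta r_i = N^d_i/\Delta t_d - N^s_i/\Delta t_s$ between
  the delay window and a spontaneous window before loading.
* `tmax_estimate()` evaluates the analytic maximal limit-cycle period
  $T_{max} = \tau_d \ln\frac{\tau_f/\tau_d}{1-U}$ (445.1 ms at defaults),
  and `capacity_estimate()` the item capacity $N_c = T_{max}/t_s$, with
  $t_s$ measured by `ps_spacing()` as the median interval between
  consecutive population spikes pooled across the held populations.
* `count_held_items()` calls a loaded population *held* over a window if
  its PS train has no gap (including the window edges) exceeding
  `gap_factor` (default 2) times $T_{max}$ — a reproducible,
  threshold-explicit version of "maintains synchronous reactivation".

## Numerical choices

* Event ordering within a step: due deliveries are added to the synaptic
  currents first, then all membranes are propagated, then thresholds are
  checked; a delivery therefore acts from the beginning of its arrival
  step. Delays are rounded *up* to the grid.
* Threshold detection at step boundaries only, without sub-step
  interpolation; at $dt = 0.05$ ms the resulting jitter is far below every
  quantity of interest (verified by the dt-halving robustness check).
* The degenerate case $\tau_m = \tau_{syn}$ of the propagator and of
  $\alpha$ uses the $t e^{-t/\tau}$ limit forms.
* Initial membrane potentials are drawn uniformly on $[0, V_{th})$ under
  the run seed (the model does not specify them); the first second of any
  run is treated as settle-in and excluded from measurement windows.
* Determinism: network construction uses R's RNG under `set.seed`;
  in-run noise uses a private 64-bit Mersenne Twister seeded from
  `sim_params()$seed`. Identical inputs give identical rasters.
* STP trace averages are taken over a capped random subset (default
  10,000) of a population's outbound plastic synapses; the subset mean is
  indistinguishable from the full mean at the reported precision.

## Problem sizes used in tests and reproduction scripts

The packaged acceptance script runs the full 8000E/2000I network for the
regime anchors (spontaneous rate, PS intervals, rate differences, and the
three-item spacing). The test suite exercises the same machinery on the
full network where a criterion requires it and otherwise on scaled
fixtures built by `make_fixture()`, which shrink neuron counts while
preserving each neuron's in-degrees — and therefore its input statistics —
so that regime behaviour carries over qualitatively after recalibrating
the background by the same procedure.

## What the fixtures do and do not show

`make_fixture()` networks (typically 10% scale) reproduce the mechanism —
loading, facilitation, winner-take-all, population spikes — but not the
quantitative anchors: with 80-neuron populations, finite-size fluctuations
both trigger and terminate reactivation more easily than at full scale.
Tests on fixtures therefore assert qualitative structure (existence,
ordering, determinism, bounds), and quantitative assertions run on the
full network.

## Known limitations

* Item encoding is idealized: selective populations are predefined and
  equally potentiated; there is no learning during the simulation.
* Heterogeneity is limited to the wiring draw: $U$, $\tau_f$, $\tau_d$
  are global scalars, and all neurons of a class share parameters.
* The calibrated operating point reproduces the regime structure with a
  somewhat longer inter-PS interval than the depression time constant
  (as observed in the source experiments) but the exact interval depends
  on the realized network and seed at the ±20% level.
* Conductance-based synapses, structural plasticity and distance-dependent
  connectivity are out of scope.
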