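---
title: "How a GluN2C/D-like NMDA conductance reshapes rate and temporal coding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How a GluN2C/D-like NMDA conductance reshapes rate and temporal coding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdagain)
```

## The scientific question

Neurons of the inferior colliculus (IC), the auditory midbrain hub, sit at
the transition from the temporal codes of the brainstem (spikes locked to
the stimulus envelope) to the rate codes of cortex. Many IC neurons —
including VIP neurons, an excitatory principal class — express NMDA
receptors containing GluN2C or GluN2D subunits. These receptors are
largely insensitive to voltage-dependent Mg²⁺ block, so they pass current
at resting potential, and their kinetics are slow, which widens the time
window over which successive synaptic inputs sum. `nmdagain` implements a
complete in-silico pipeline for asking what such a conductance does to the
way a neuron encodes periodic input trains: does it shift the rate
modulation transfer function (MTF) upward (additive gain), and at what
cost to spike-timing precision (the temporal MTF)?

## The model neuron

The core is a single-compartment conductance-based neuron of the
Wang–Buzsáki fast-spiking type, chosen because it fires sustained trains
over a wide input range, like VIP neurons in vitro:

$$C_m \frac{dV}{dt} = -I_{Na} - I_K - I_L - I_{syn} + I_{app}$$

with $I_{Na} = g_{Na}\, m_\infty^3\, h\,(V - E_{Na})$,
$I_K = g_K n^4 (V - E_K)$, $I_L = g_L (V - E_L)$, instantaneous Na⁺
activation $m_\infty = \alpha_m/(\alpha_m + \beta_m)$, and first-order
h/n kinetics scaled by $\phi$. Defaults: $C_m = 1\ \mu F/cm^2$,
$g_{Na} = 35$, $g_K = 9\ mS/cm^2$, $E_{Na} = 55$, $E_K = -90$,
$E_L = -65$ mV. The rate constants are implemented in
`rate_functions()`; their two removable singularities (at $-35$ and
$-34$ mV) are evaluated as their finite limits whenever the argument is
within $10^{-7}$ mV of the singular point.

Two parameters deserve comment because the model family leaves them
open:

* **$\phi = 5$** — the gating-rate scale of the original fast-spiking
  interneuron model; exposed in `membrane_params()`.
* **$g_L$** — the leak conductance is the biological knob for
  neuron-to-neuron diversity in input resistance. For a spherical soma
  of diameter $d$ the conversion is $R = 1/(g_L \pi d^2)$
  (`membrane_resistance()`); with $d = 15\ \mu m$, the sweep values
  0.282, 0.50, 0.75, 1.99 and 5.3 mS/cm² correspond to 502, 283, 189,
  71 and 27 MΩ, and the reference VIP-neuron value 0.7 mS/cm² to
  ~200 MΩ. The sphere-surface convention $A = \pi d^2$ is the one that
  reproduces all five printed resistances.

### Numerical integration

A fixed-step classical Runge–Kutta (RK4) scheme with dt = 0.01 ms,
implemented in C++. Fixed-step integration makes every result
bit-reproducible; the step is small enough that halving it changes no
spike count and moves spike times by ~10⁻⁴ ms (tested). Synaptic
conductance waveforms are precomputed on the half-step grid so the RK4
midpoint evaluations use exact samples rather than interpolations. The
simulation starts from the root-found resting state (`resting_state()`,
a fixed point solved to 10⁻¹⁰), which removes onset transients without
needing an equilibration period; non-finite state at any step raises an
explicit integration-failure condition naming the failure time. Gating
variables never leave $[0,1]$ (asserted to 10⁻⁹ in the tests), and with
$g_{Na} = g_K = 0$ the integrator reproduces the analytic RC charging
curve to better than 10⁻⁶ relative error.

## The synapse

Each input pulse contributes a normalised dual-exponential conductance

$$g(t) = g_{max}\, N\, (1 - e^{-t/\tau_{rise}})\, e^{-t/\tau_{decay}},$$

with $N$ chosen analytically so a single pulse peaks exactly at
$g_{max}$ (peak time $t^* = \tau_{rise}\ln(1 + \tau_{decay}/\tau_{rise})$).
Trains sum linearly across pulses; the summation is computed by an exact
two-exponential recursion, so the waveform at every grid point equals
the closed-form superposition even for onsets falling between grid
points.

Kinetics defaults (all configurable in `synapse_params()`):

| conductance | τ_rise | τ_decay | rationale |
|---|---|---|---|
| AMPA | 0.2 ms | 2 ms | fast AMPA typical of auditory neurons |
| NMDA (GluN2D-like) | 5 ms | 100 ms | top of the 10–100 ms decay range reported for the recorded currents |

The NMDA conductance has **no Mg²⁺ block term** — that is the defining
property of the GluN2C/D-like receptor being modelled — and its peak is
25% of the AMPA peak (`nmda_ratio = 0.25`). The synaptic current uses
the instantaneous driving force $I_{syn} = (g_{AMPA} + g_{NMDA})(V -
E_{syn})$ with $E_{syn} = 0$ mV, the standard glutamatergic reversal.

### NMDA saturation

A design point that implementation forced us to confront: with *purely
linear* superposition, a 100 ms decay at a 512 Hz input rate accumulates
to ≥ 15× the single-pulse peak — and, measured against this model's
input–output curve, a sustained conductance of that size drives the
neuron into depolarisation block at *every* membrane resistance. Real
NMDA receptor populations cannot do this: once the available receptors
are bound and open, the conductance is at its maximum. We therefore treat
the 25% figure as what it is for a gating-variable synapse — the
*maximal* NMDA conductance — and cap the summed NMDA waveform at
`nmda_ratio * g_ampa` (`nmda_saturation = TRUE`, the default). Below the
cap summation is exactly linear; the AMPA component, whose fast decay
never accumulates appreciably, always sums linearly. With the cap in
place the NMDA conductance behaves as a tonic, frequency-limited boost —
which is precisely the "additive gain" phenomenon under study — while
uncapped behaviour remains available (`nmda_saturation = FALSE`) for
studying the linear-summation limit.

## Calibrating synaptic strength

No absolute synaptic conductance is part of the study conditions; what is
specified is the *regime*. `calibrate_synapse()` finds, by bisection, the
minimal single-pulse AMPA conductance that fires the neuron from rest,
and sets `g_ampa` to a multiple of that threshold:

* **High-resistance cells (gL ≤ 1 mS/cm²): 0.85 × threshold.** Single
  EPSPs are subthreshold, so any spiking during a train must arise from
  temporal summation. This is the regime in which a 16 Hz AMPA-only
  train produces only phase-locked EPSPs while adding the NMDA
  conductance yields phase-locked action potentials. The value sits
  safely below threshold while keeping the combined AMPA+NMDA drive
  below the peak of the model's input–output curve at the top input
  frequency — at 0.9 the drive at gL = 0.75 lands just past that peak
  and the gain at 512 Hz inverts, which the underlying experiments do
  not show for high-resistance cells.
* **Low-resistance cells (gL > 1 mS/cm²): 2 × threshold.** Leaky
  neurons in this preparation fire one temporally precise spike per
  input pulse, which requires suprathreshold single inputs; subthreshold
  pulses into a membrane with a sub-millisecond time constant would
  never sum to threshold at any frequency. In this regime adding the
  tonic NMDA conductance inactivates the Na⁺ current and collapses the
  response to a single onset spike per train (depolarisation block) at
  high input frequencies, reversing the sign of the NMDA effect.

`run_sweep()` applies this schedule per leak value (`calibration_scale()`),
and both the scale and the calibrated conductances are recorded in the
result table.

## The in-silico experiment

```{r sweep, eval = FALSE}
mtf <- run_sweep(membrane_params(), synapse_params(),
                 gl_values = c(0.282, 0.50, 0.75, 1.99, 5.3))
autoplot(mtf)
```

One second input trains, 16–512 Hz on a geometric grid at 4 steps per
octave (21 frequencies), in the AMPA-only and AMPA+NMDA conditions —
210 rows for the five-leak sweep. Per row: firing rate, spikes per
train, vector strength, mean phase. The model is deterministic, so a
single repetition per condition suffices and re-running a sweep yields
an identical table.

### Response metrics

* **Vector strength** $VS = \frac{1}{N}\left|\sum_k e^{i 2\pi f
  t_k}\right|$, the mean resultant length of spike phases. Phase zero is
  the input-pulse onset. Following the convention for sparse responses,
  VS is *undefined* — reported as `NA`, never as 0 — unless a train
  elicits more than 4 spikes (`min_spikes = 5`, a strict reading of the
  rule).
* **Mean phase**: circular mean in $[0, 2\pi)$, same spike-count gate.
* **Spike detection**: upward crossings of 0 mV with a 1 ms lockout —
  unambiguous for full-height action potentials.
* **Evoked / spontaneous rate** (`response_rates()`) and **dynamic
  range** (max − min rate across the MTF) for analysing responses to
  repeated stimuli.
* **`classify_response()`** labels a frequency series "onset" when the
  count is exactly 1 spike/train across the whole top octave,
  "sustained" otherwise, and "anomalous" if the top frequency yields
  zero spikes (which depolarisation block never produces — the onset
  spike always survives).

## Waveform analysis

Synaptic events (EPSCs/EPSPs) are quantified two ways, deliberately
redundant so each can check the other:

1. **Model fit** (`fit_epsc()`): bounded Levenberg–Marquardt least
   squares of $f(x) = y_0 + amp\,(1 - e^{-(x-x_0)/\tau_{rise}})
   e^{-(x-x_0)/\tau_{decay}}$. Initialisation: baseline mean, extremum,
   10%-deviation crossing, $\tau_{rise} = 1$ ms, $\tau_{decay}$ from the
   half-decay time. The fit errors out rather than returning a
   non-converged or degenerate (flat-trace) result.
2. **Direct measurement** (`measure_waveform()`): amplitude as extremum
   minus baseline mean, halfwidth between interpolated half-amplitude
   crossings, rise time between the 10% and 90% crossings (configurable
   to 20–80%; the convention is stated because the upstream literature
   rarely is), decay τ by a single-exponential fit from the peak to the
   5%-of-amplitude return.

Sweeps are averaged pointwise (`average_sweeps()`) before measurement.
Temporal summation of a pulse train (`summation_metrics()`) is
quantified by the per-pulse peak amplitudes *measured from the common
pre-train baseline* — summation appears as successively larger peaks —
and by the trapezoidal area under the baseline-subtracted curve from the
first onset to one inter-pulse interval past the last. An optional
zero-phase Butterworth low-pass stage (`lowpass_trace()`) mirrors the
usual conditioning of recorded data; synthetic tests run unfiltered.

## Co-expression tabulation

`summarize_expression()` tabulates per-cell RNAscope marker tables: a
cell is positive for a transcript when ≥ 1 punctum co-localises with its
tdTomato signal, the four exclusive classes (only-Glun2d, only-Glun2c,
both, neither) partition the tdTomato⁺ population exactly, and
percentages are counts over tdTomato⁺ rounded **half-away-from-zero** to
one decimal — the rule that reproduces every printed percentage when
recomputed from the published counts (shipped as plain-text tables,
`glun2_slice_counts()` / `glun2_subdivision_counts()`).
`marker_table_from_counts()` reconstructs a minimal per-cell table from
group marginals and is exact round-trip by construction.
tdTomato-negative rows are retained but never enter denominators.

## Synthetic data

Every analysis stage can be exercised without external data:

* `gen_phase_locked_spikes()` — inhomogeneous point process with a von
  Mises intensity profile, drawn by thinning a homogeneous process
  (exact, fully seeded). The von Mises concentration maps monotonically
  to vector strength via $VS = I_1(\kappa)/I_0(\kappa)$, inverted by
  `kappa_for_vs()`, so trains with a target VS can be generated
  directly; κ = 0 gives a homogeneous (unlocked) train.
* `gen_epsc_trace()` — the exact forward model of the fit equation plus
  iid Gaussian noise.
* `gen_marker_table()` — multinomial class draws per cell with
  published-proportion defaults (0.843 / 0.010 / 0.071) and shifted-
  Poisson puncta counts for positive channels.

What the generators deliberately do *not* emulate: refractoriness and
serial ISI correlations of real spike trains, non-Gaussian and
correlated recording noise, drift, and any generative model of the
in-vivo pharmacology experiment. Passing tests therefore validate the
*estimators* and the *model pipeline*, not the claim that real IC data
follow these generative forms.

## Problem sizes and numerical choices

The shipped tests and sweeps use 1 s trains at dt = 0.01 ms, the full
21-frequency grid over five leak values for the acceptance properties,
200 replicates for the noisy-fit recovery study, and 10⁴-spike trains
for the vector-strength null — sizes at which every stochastic check
sits several standard errors from its pass boundary. Bisection
calibration uses a 60 ms single-pulse probe and a 10⁻³ relative
tolerance. Ties and degenerate inputs are handled explicitly: zero-rate
generators return empty trains, empty groups yield `NA` percentages
(never 0), flat traces refuse to fit, and windows of zero length are
rejected.

## Known limitations

* Single compartment; no dendritic filtering or synapse placement.
* No low-voltage-activated K⁺ or other additional conductances — the
  target cell class shows sustained firing where these are not
  prominent, but this choice means onset responses here arise only from
  Na⁺ inactivation.
* No short-term plasticity or stochastic vesicle release; input trains
  are perfectly periodic.
* The NMDA saturation cap is a pointwise ceiling, not a kinetic gating
  scheme; the two coincide for a single pulse and in the
  frequency-saturated limit but differ in the approach to the ceiling.
* Published MTF curves are not point-reproducible (the original
  synaptic strengths are not recoverable), so model-level claims are
  validated as qualitative regime properties, not curve fits.
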