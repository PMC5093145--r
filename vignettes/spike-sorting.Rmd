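---
title: "Methods: a memristive spiking network for unsupervised spike sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a memristive spiking network for unsupervised spike sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snnsort)
```

This vignette documents the model implemented by `snnsort`, the assumptions
behind it, the provenance of every tunable constant, and the limits of what
the synthetic benchmarks establish.

## 1. Signal model and encoder

The input is a uniformly sampled single-channel extracellular voltage trace.
Action potentials appear as stereotyped 1–2 ms transients whose spectral
energy lies below ~3 kHz; slower components (field potentials, movement
artifacts) live below 100 Hz. The trace is max-abs normalized to [−1, 1]
(`normalize_trace()`); all neuron thresholds are expressed in these arbitrary
units. A causal streaming variant (running max over a trailing window) exists
for online use, since a global maximum is not available in real time.

The encoder (`encode()`) is a bank of `n_filters = 32` band-pass filters with
center frequencies linearly spaced from 100 to 2000 Hz (adjacent spacing
1900/31 ≈ 61.3 Hz, matching the ~60 Hz per-filter bandwidth so the band is
tiled without gaps or heavy redundancy), each realized as a 2nd-order
Butterworth band-pass and applied **causally** (single pass, not zero-phase).
Zero-phase filtering would look ahead in time; a real-time sorter cannot.
Outputs are full-wave rectified. Two physical facts motivate the design:

- sub-100 Hz interference is rejected by construction, so no separate spike
  detection or high-pass stage is needed;
- distinct spike shapes concentrate energy in distinct subsets of bands,
  giving linearly separable "finger prints".

Narrow bands trade temporal for spectral resolution. For a 60 Hz-wide
2nd-order band-pass the impulse response decays to 5 % of its peak in
~20–31 ms and to 1 % in ~41–44 ms (dominant pole pair ≈ ln(100)/(π·60) s).
That is short enough to resolve spikes arriving a few tens of milliseconds
apart, which is the operating regime here, but it *does* smear very close
doublets; raising the bandwidth would sharpen time at the cost of frequency
discrimination. Filters whose passband would cross 0 Hz or Nyquist are
clipped with a warning. The filter design (analog Butterworth prototype,
lowpass→bandpass transform, bilinear transform with pre-warping) is
implemented in the package because no filter-design package is available in
the supported dependency set; it was verified coefficient-for-coefficient
against an independent reference implementation, and the test suite checks
the realized magnitude response against a sinusoid-probe oracle.

## 2. Neurons

Both layers use the three-parameter leaky integrate-and-fire model: the
integration decays by `exp(−dt/t_leak)` each step, accumulates non-negative
drive, fires on reaching `i_thres`, hard-resets to 0 and freezes for an
absolute refractory period. Published values are used as defaults:

| layer | `i_thres` (a.u.) | `t_leak` | `t_refractory` |
|---|---|---|---|
| input (×32) | 0.1 | 0.2 ms | 4 ms |
| output (×5) | 0.58 | 5.1 ms | 46.1 ms |

Two details are deliberately pinned down where the source model is silent:

- **Reset is to zero** (not subtractive) and the refractory period is
  absolute (state frozen, inputs ignored). This is the simplest LIF
  consistent with three parameters.
- **Leak is exponential**, per the standard formulation of the model.

The simulation is clock-driven at the trace sampling rate (default 20 kHz,
`dt = 50 µs`), finer than every time constant in the system. A pure-R
reference engine mirrors the compiled loop draw-for-draw and is tested to be
bit-identical on short traces; the clock-driven dynamics are also tested
against an analytic event-driven oracle to 1e-9 relative tolerance.

**Layer-1 drive and the input gain.** Input neuron *k* receives
`rectified_channel_k × dt × input_gain` per step (amplitude–time
integration). With the published layer-1 constants, the steady-state
integration for a channel of amplitude *A* is ≈ `A × t_leak × input_gain`;
with gain 1 this is ~2×10⁻⁴·A, so a unit-gain network is silent for any
normalized input — the gain is a required calibration constant standing in
for the analog front-end gain of a hardware system (whose input-layer tuning
was likewise manual). The default `input_gain = 45000` puts the layer-1
firing cutoff at channel amplitude ≈ 0.017, between the band-limited noise
floor (~0.006–0.011 for the default synthetic world) and the weakest spike's
channel amplitude (~0.03), so layer-1 firing tracks band energy, as intended.

## 3. Synapses

One synaptic weight is `n_devices = 10` binary resistive devices in parallel.
Each device is LRS (low resistance) or HRS (high resistance); every
programming pulse re-samples its resistance from the state's log-normal
distribution (cycle-to-cycle variability). Defaults: median LRS 25 kΩ, median
HRS 250 kΩ (a one-decade window, as observed for abrupt switching at 30 µA
compliance), `sdlog` 0.3 / 0.5. The medians' window is from the source
device data; the spreads are behavioral calibration constants, since the
underlying distributions are published only as figure panels.

The normalized weight is `(G_total − G_min)/(G_max − G_min)` clipped to
[0, 1], with `G_min`/`G_max` the all-HRS/all-LRS sums at the medians. With
zero spread the weight takes exactly n+1 levels; with realistic spread the
levels blur, which is the intended "approximately n + 1 states" behavior.
Devices start LRS with probability 1/2, so untrained weights scatter around
0.5 and the untrained network responds unspecifically — the bootstrap for
unsupervised learning.

A presynaptic spike delivers `weight × synaptic_gain` to every output
integrator and costs one Read per device (energy `V_read²/R · t_read` per
device, ~0.4 pJ at LRS). `synaptic_gain = 0.10` (calibrated, see §6) sets how
many coincident presynaptic spikes an output needs to reach threshold:
~12 spikes at weight 0.5 within the 5.1 ms leak window, half that at weight 1.

## 4. Plasticity and winner-take-all

When output neuron *j* fires at `t_post`, every afferent synapse is updated:

- `t_post − t_pre < t_LTP` (input recently active): each HRS device is Set
  independently with probability `p_set` — gradual LTP;
- otherwise (including inputs that never fired): each LRS device is Reset
  with probability `p_reset` — gradual LTD.

Per-device (not per-synapse) coin flips are essential: they turn binary
devices into a gradual multi-level weight (expected LRS fraction after k LTP
events from all-HRS is `1 − (1−p_set)^k`, verified by Monte-Carlo in the test
suite). Set/Reset pulses cost 75/45 pJ each and count toward endurance; a
pulse into a device already in the target state still costs a pulse.

Lateral inhibition is implemented as winner-take-all: if one or more outputs
cross threshold in a step, only the most excited fires (ties to the lowest
id); all others are reset to zero and inhibited for `inhibition_s`. One
output spike per time step, maximum, under any input.

## 5. Synthetic world

`generate_recording()` emulates a nerve recording with known ground truth:

- two deterministic templates ("A": biphasic, ~1.1 ms, energy near 1.3 kHz;
  "B": triphasic, ~2.2 ms, near 450 Hz) with band-energy finger prints whose
  cosine similarity over the default bank is < 0.95;
- per-unit Poisson event times (default 3.3 Hz — the rate implied by "50
  events in 15 s" in the source recordings, i.e. tens of events per 10 s)
  thinned by a 10 ms refractory period; linear superposition, so overlapping
  spikes occur naturally;
- white Gaussian noise (σ = 0.05 against unit template peaks — a clean
  nerve recording; a pink-noise option emulates noisier preparations) plus a
  low-frequency sinusoid (0.2 amplitude at 7.5 Hz) standing in for field
  potentials;
- the default staged protocol is the source protocol scaled by 0.1 in time:
  B active 0–68.1 s, A only 28.5–54.5 s, so the network must first learn one
  class, then discover a new one, then tolerate its disappearance.

Amplitude/noise defaults are calibration constants (no SNR figures are
published for the original recordings). What the generator does **not**
emulate: electrode drift, bursting statistics, more than a handful of units,
spike-shape variability within a unit, and correlated network noise. A green
synthetic benchmark therefore establishes the mechanism (encoding →
unsupervised separation → stable assignment), not field performance on any
particular preparation.

## 6. Calibrated constants and their rationale

The output-layer and plasticity constants of the original system were tuned
by a genetic algorithm and never published; this package must choose its own.
They were calibrated by randomized search over five generator seeds,
maximizing the worst-case per-unit recognition, and then frozen:

- `p_set = 0.3`, `p_reset = 0.05`, `t_ltp = 10 ms`. The LTP window spans a
  spike plus the useful part of the filter transient. The relatively high Set
  probability makes a neuron commit to a class within ~15–20 of its own
  spikes; the desk-scale protocol offers ~10× fewer events per phase than the
  original 681 s recording, so learning must lock proportionally faster to
  reproduce the same relative dynamics.
- `inhibition_s = 47 ms`, just above the 46.1 ms output refractory period.
  This is the load-bearing choice. With short inhibition (a few ms), whenever
  two events of the same unit arrive within one refractory period, the
  assigned neuron is refractory for the second event and a *different* neuron
  wins it — and since that event looks exactly like the class, the second
  neuron gradually potentiates into a clone of the first, splitting the
  class and leaving "spare" neurons noticeably active. Inhibition that
  outlasts the refractory period means refractory-shadowed events get no
  response at all: a bounded recognition loss instead of a corrupted
  assignment. Duplicate-class suppression is exactly what the recurrent
  inhibition is for; only its duration is this package's choice.
- `input_gain = 45000`, `synaptic_gain = 0.10` (see §2–3).

**Attainable recognition.** With Poisson events at 3.3 Hz and a 46.1 ms
refractory, ~11 % of same-unit gaps fall inside the refractory period and
~6–8 % of events fall inside the other unit's inhibition shadow; late
responses inside the 20 ms window rescue part of both. The attainable mean
recognition rate is therefore ≈ 0.85–0.90, not 1.0 — the same physics that
caps the original system's reported ~86 % on real data. Because the loss is
dominated by the seed's particular gap realization, the measured rate varies
by several percentage points from seed to seed and can dip toward ~0.75 on
unlucky realizations; the default seed-1 dataset yields B = 0.916, A = 0.805
(recomputed by `scripts/acceptance.R` and the test suite at every run).

## 7. Numerical and bookkeeping choices

- Refractory/inhibition intervals are closed on the right: a neuron frozen
  until `t_r` resumes at the first step strictly after `t_r` (so constant
  suprathreshold drive yields inter-spike interval `t_ref + dt`).
- The recognition window is half-open, `(t, t + 20 ms]`: a spike exactly at
  the event time is not causal and does not count.
- Recognition bins with zero truth events are excluded from the mean, so the
  mean effectively starts at a unit's first appearance.
- Neuron-to-unit assignment is greedy and injective, by descending match
  count, ties to the lower neuron id.
- All randomness fans out from one master seed through named substreams
  (synthetic data, initial device states, run-time plasticity coins), so
  every result is bit-identically reproducible; the compiled and R engines
  consume the random stream in the same order.
- Endurance extrapolation uses a 365-day year (3.1536×10⁸ s per decade).
- The energy report prints `P = E_total/duration`; with the published event
  counts and per-event energies this gives ≈ 16 nW over 681 s, whereas the
  source table prints 8.1 nW for the same inputs — the divisor used there is
  not stated, so the package documents and keeps the literal `E/t`.
- The source text gives the mean recognition rate as 85.5 % while the
  corresponding figure caption says 86.4 %; the discrepancy is inherited from
  the source and simply noted.

## 8. Genetic-algorithm tuner

`ga_optimize()` reproduces the published tuning procedure in miniature:
multiplicative mutation of each parameter by `1 + u`, `u ~ U(−v, v)` with
`v ≤ 0.2` ("maximum 20 % variation"), four winners per generation kept
unchanged (elitist, so the best fitness never decreases), and `v` halved
whenever the best fitness improves by less than 1 % — "variation decreased as
the classification rate saturated". Population size and generation counts
were not published; defaults (16, 10) are small enough for desk use. Layer-1
and filter parameters are excluded from the search, as they were tuned
separately in the original system.

## 9. Known limitations

- Recognition is capped by refractory and inhibition shadowing at realistic
  event rates (§6); the package reports the honest `E/t` power and per-bin
  rates rather than optimistic summaries.
- The device model is behavioral: binary states, log-normal resistance
  sampling, fixed pulse energies. No filament physics, no gradual
  low-current switching mode, no read disturb, no retention loss.
- Single channel, two layers, excitatory plastic synapses only; no synaptic
  or axonal delays; no hardware timing jitter.
- The desk-scale protocol (68 s) compresses the original staged experiment
  tenfold; constants that depend on absolute event counts (learning lock-in)
  were recalibrated accordingly and would need retuning for full-length
  recordings.
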