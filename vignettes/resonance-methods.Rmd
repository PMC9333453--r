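---
title: "Modeling neuronal resonance across levels of organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neuronal resonance across levels of organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurores)
```

## Scope

`neurores` simulates how resonance — a maximal response to periodic input in
a limited, non-zero frequency band — arises in neuronal systems at four
levels of organization: membrane potential fluctuations, single-neuron
spiking, short-term synaptic dynamics, and small networks. The package
provides six cell models, a fixed-step integrator with threshold spiking,
stimulus generators, network motifs, and the spectral metrics used to
quantify spiking resonance. This vignette documents the models, the
numerical choices, and the design decisions a user should know before
interpreting results.

## Models

All models follow the conductance-based formalism in units of mV, ms,
μA/cm², mS/cm² and μF/cm². Six cells are provided:

* **`naph_cell()`** — a 2D subthreshold resonator: leak, persistent sodium
  with instantaneous activation (`g_p p∞(V)(V−E_Na)`), and an h-current
  (`g_h r (V−E_h)`, voltage-independent `τ_r = 100` ms), plus
  threshold–clamp–reset spiking. The membrane RC acts as a low-pass filter,
  the h-current (with leak) as a high-pass filter, and the persistent sodium
  current amplifies the band-pass; the impedance magnitude peaks near
  7.5 Hz.
* **`lif_cell()`** — leaky integrate-and-fire. Subthreshold it is a pure
  low-pass filter; at spiking drive the after-spike reset enforces one spike
  per cycle over a range of frequencies ("spike discretization"), a
  spiking-level high-pass filter.
* **`calcium_lif_cell()`** — LIF plus a spike-triggered calcium current:
  each spike sets `N_C ← N_reset`, which slowly opens the calcium gate `K`
  (`τ_act/N_C` activation, `τ_inact` inactivation) while `N_C` decays with
  `τ_deact`, transiently lowering the effective threshold for spikes that
  arrive within that window.
* **`plastic_lif_cell()`** — LIF driven through an AMPA-like gate `S` with
  short-term depression `D` (low-pass) and facilitation `F` (high-pass);
  the product `D·F` is the probability of presynaptic release.
* **`pyr_cell()`** — a 4D pyramidal cell (transient sodium with
  instantaneous `m∞(V)³` activation, delayed-rectifier potassium,
  h-current); full spike waveforms.
* **`int_cell()`** — a Wang–Buzsáki interneuron extended with a
  non-inactivating M-like potassium current whose kinetics are ten times
  faster than the classical M-current, giving gamma-band (≈40 Hz)
  subthreshold resonance at depolarized operating points.

Gating equations with removable singularities (`a(V+c)/(1−e^{−(V+c)/b})`)
are evaluated as their limit `a·b` at `V = −c`. For the M-like gate we use
`τ_q(V) = 40/(3.3 e^{(V+35)/20} + e^{−(V+35)/20})`, the canonical M-current
form sped up tenfold; with this form the interneuron's impedance peaks at
≈40 Hz, consistent with the behavior the model is designed to show.

## Integration and spiking

All models are advanced with the explicit second-order Runge–Kutta endpoint
(modified Euler) method at a fixed step (`dt = 0.1` ms for the
integrate-and-fire studies, `0.025` ms for the biophysical PYR/INT
studies). For the integrate-and-fire cells, a spike is logged when `V >
V_th` after a full step; `V` is then clamped at `V_peak` for `T_spike`
(auxiliary states keep evolving with `V = V_peak`, so spike-driven
variables see the depolarization), then reset to `V_reset` with any
auxiliary resets (e.g. `N_C ← N_reset`) applied. Intra-step crossings are
not interpolated, keeping spike times on the grid. The biophysical cells
produce full spike waveforms; spike times are logged at upward crossings of
0 mV.

**Noise.** Membrane-potential variability is an additive current
`g_N·η`, `η ~ N(0, σ)`, drawn once per step and entering the voltage
derivative identically in both RK2 stages. The draw is *not* scaled by
`√dt`: `σ` is the per-step noise amplitude at the model's fixed `dt`, so
results are `dt`-dependent by construction and each scenario's `dt` is part
of its preset. Streams are keyed by `(master_seed, cell_id, trial_id)`, so
every cell and trial is independent and any trial is reproducible in
isolation; with `σ = 0` the pipeline is bit-deterministic.

**Initial conditions and settling.** Cells start at the resting state of
their steady-state I–V curve under the DC bias (the most hyperpolarized
zero, all gates at `x∞(V)`), with `S = 0`, `D = 1`, `F = 0` (disabled
plasticity factors pinned at 1) and `K = N_C = 0`. A settling period
(default 1 s) precedes every metric window; for chirp protocols the settle
runs at the DC bias before the sweep starts. The threshold mechanism is
armed only after the settle. This matters for the subthreshold resonator:
its printed parameter set has, besides the stable subthreshold fixed point,
a reset-driven firing loop (the deep reset recharges the h-current gate,
which re-depolarizes the cell), and a cold start from `V = E_L` would latch
into that loop before the experiment begins. Arming after the settle
guarantees the measurements start from the physiological operating point.

## Stimuli and synthetic spike trains

Inputs are sinusoids `I_bias + A_in sin(2πft)` and linear chirps
`I_bias + A_in cos(π + 2πf₀t + π(f₁−f₀)t²/T)` whose instantaneous frequency
ramps linearly from `f₀` to `f₁`. Periodic spike trains place one spike at
each waveform maximum, located analytically from the phase function.
Presynaptic voltages are two-level traces: 50 mV whenever a spike occurred
within the last 1 ms, −60 mV otherwise; spikes closer than 1 ms merge into
one longer pulse.

`make_synthetic_trains()` generates the two canonical test beds for the
metrics: *rate-band* trains (Poisson per-cycle counts with the mean doubled
inside a band, uniform phases — pure cycle-averaged firing-rate resonance)
and *phase-band* trains (fixed counts, von Mises phases with elevated
concentration inside the band — pure spike-timing resonance). These
synthetic data emulate band-limited rate or phase structure only; they do
not contain refractoriness, bursting, adaptation, or rate–phase coupling,
so passing tests on them validates the metrics, not the realism of any
biological spike train.

## Short-term plasticity: release semantics

The depression and facilitation ODEs,
`dD/dt = −H(V_pre) D/τ_reset(d) + (1−D)/τ_dep` and
`dF/dt = H(V_pre)(1−F)/τ_reset(f) − F/τ_fac` with
`H(V) = (1+tanh(V/4))/2`, reset `D → 0` and `F → 1` essentially completely
during each 1 ms presynaptic pulse (`τ_reset ≪ 1` ms) and relax between
pulses. Taken literally, a conductance `g_S·S·D·F` with contemporaneous
factors would transmit almost nothing: `D` collapses while `S` is still
rising, and the overlap suppresses the EPSP roughly sevenfold, abolishing
every downstream phenomenon the model exists to show. The package therefore
treats `D·F` as what it is described to be — the probability of
presynaptic release — and samples it at the onset of each presynaptic
pulse, before the pulse enters the integrator: the conductance is
`g_S·S·Rel` with `Rel = D·F` held over the pulse and its EPSP, while the
printed ODEs continue to govern `D` and `F`. Depression and facilitation
triggered by a spike thus affect subsequent spikes, not the concurrent
release. With this reading the EPSP magnitude profile peaks near 8 Hz,
depression-only profiles are low-pass, and facilitation-only profiles are
high-pass. The absolute synaptic efficacy implied by the reference
conductances is strong (unitary EPSPs of order 10 mV); downstream
coherence magnitudes are correspondingly closer to saturation than to the
weakly-locked regime, a known limitation discussed below.

## Networks

Three motifs are provided through `build_preset()`: all-to-all E/I networks
(16 driven excitatory cells onto 4 noisy integrate-and-fire targets, one
synaptic gate per presynaptic cell, class conductances
`g_ee, g_ei, g_ie, g_ii` with AMPA 0.1/3 ms and GABA_A 0.3/9 ms kinetics);
a 3-layer diverging/converging feedforward network (a point-process source
firing once per chirp cycle, 50 identical plastic-synapse LIF cells with
independent noise, one noiseless output LIF); and feedforward inhibition
(interneuron → pyramidal cell through a single GABA_A synapse, `g_ei =
0.4`, all other connections zero). The layer-1 source is a spike train
encoded as a presynaptic voltage, not an ODE cell. Self-synapses implied by
the all-to-all notation are included exactly where a preset gives them
non-zero conductance (`g_ii`). Feedforward structure is verified by test:
severing or perturbing downstream elements leaves upstream spike trains
bit-identical.

## Metrics

* **Impedance.** For single-frequency runs, `|Z|(f) = (max V − min V)/(2
  A_in)` over the post-settle window, with the phase taken from the
  fundamental Fourier component of `V` relative to the input (equivalent to
  the peak-lag for clean sinusoidal steady states and far more robust).
  For chirp runs, the ratio of Fourier transforms of the mean-subtracted
  voltage and current, magnitude-smoothed over a configurable bandwidth
  (default 2 Hz); the series is truncated to the nearest 5-smooth length so
  the FFT never degenerates to a near-prime-length DFT.
* **Cycle-averaged rate and fingerprint.** Spikes are assigned to the
  analytic instantaneous frequency and phase of the stimulus (phase 0 at
  the waveform maximum; no Hilbert transform). The fingerprint divides
  pooled spike counts by per-bin occupancy (1 Hz × 36 phase bins/cycle by
  default); its phase-marginal reproduces the cycle-averaged rate, and
  `expand_phase()` renders the conventional 1.5-cycle axis.
* **Spike–input coherence.** Welch segment averaging: 2 s Hann-tapered,
  50%-overlapping segments (0.5 Hz resolution), cross-spectra pooled over
  segments and trials before forming `|S_xy|/√(S_xx S_yy)`; spike trains
  enter as binned indicator series on a 1 ms grid (Nyquist 500 Hz, far
  above every band studied). Coherence is bounded in [0, 1], reaches 1
  under perfect locking, and decays to the `1/n_segments` bias floor for
  unrelated trains. Absolute coherence values are estimator-dependent;
  segment length is a configurable knob. A property of this pooled
  estimator worth knowing: with chirp inputs, the input and a locked output
  concentrate their power at any analysis frequency in the same few
  segments, so coherence saturates near 1 whenever locking is strong, and
  moderate background spiking dilutes it only weakly.
* **EPSP magnitude.** Steady-state per-cycle peak-to-trough of the
  postsynaptic potential after the settle, with spiking disabled (threshold
  raised to 0 mV); one value per presynaptic rate.
* **Peaks and bands.** `find_resonant_peak()` takes the argmax after an
  optional 3-bin moving average, breaks ties toward the lower frequency,
  and flags a profile as resonant only when the peak is interior to the
  grid. `spiking_band()` finds the contiguous sustained-spiking band
  (default ≥ 1 spk/s) containing the maximum and flags bands that touch the
  low edge as low-pass.

## Problem sizes

The shipped scenarios are desk-scale: at most ~70 cells, ≤20 s of simulated
time per trial, `dt ≥ 0.025` ms, and 5–20 trials per condition; the noise
sweep uses a 0.1 mV σ grid (a documented coarsening of the 0.025 mV-step
sweep the full protocol would use; pass a finer `sigma_grid` override to
restore it). A full acceptance run completes in about a minute on one core.

## Known limitations

* The subthreshold resonator's printed parameters put its spiking threshold
  only ≈2.6 mV above the operating point at a subthreshold gain of
  ≈24 mV/(μA/cm²), so the minimal amplitude that recruits any spike is
  ≈0.094 μA/cm², and its reset loop makes sustained firing bursty rather
  than one-per-cycle once recruited.
* The calcium cell's reference drive is exactly threshold-grazing
  (`E_L + (I_bias+A_in)/g_L = V_th`), and the calcium-mediated
  depolarization at the next cycle peak is about half the membrane
  attenuation deficit, so with the reference parameters no sustained
  spiking band exists; roughly doubling the calcium strength (e.g. `g_C`)
  restores a narrow band near 8 Hz. The band machinery and the `g_C`
  sensitivity sweep are tested in that regime.
* Layer coherence magnitudes in the feedforward network sit near
  saturation (≈0.95+) rather than in a weakly-locked regime, a joint
  consequence of the strong reference synaptic efficacy and the pooled
  coherence estimator described above.
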