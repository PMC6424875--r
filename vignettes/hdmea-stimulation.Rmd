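---
title: "Single-neuron stimulation on HD-MEAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-neuron stimulation on HD-MEAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meastim)
```

## Scope

`meastim` implements the computational core of a single-neuron
electrical-stimulation workflow on CMOS high-density microelectrode
arrays (HD-MEAs): planar chips with thousands of 5 × 9 µm platinum
electrodes at 17.5 µm pitch that can both record extracellular action
potentials (EAPs, µV scale, 20 kSamples/s) and inject stimulation pulses
through the same electrodes. The package covers five connected pieces:

1. **Waveforms and charge** — construction of the stimulation pulse
   shapes used on such chips and exact charge accounting in both
   stimulation modes;
2. **Electrode interface** — an equivalent-circuit model of the
   electrode–electrolyte interface with a transient fit recovering the
   charge-transfer resistance and double-layer capacitance;
3. **Synthetic recordings** — seeded, ground-truth-annotated
   multi-electrode traces with EAP footprints, stimulation artifacts and
   stochastic evoked responses;
4. **Detection** — threshold detectors for spontaneous and evoked
   spikes, efficiency tables and 90 % activation thresholds;
5. **Field simulation** — a quasi-static finite-difference solver for
   multi-electrode stimulation configurations.

No real recordings ship with the package; the synthetic generator is a
first-class, tested component that defines the study conditions under
which everything else is validated.

## Stimulation waveforms and charge accounting

Voltage-mode protocols use monophasic (anodic or cathodic) and biphasic
pulses; amplitudes are peak-to-peak, so a biphasic pulse of amplitude
$V_{pp}$ swings $\pm V_{pp}/2$ about baseline while a monophasic pulse
carries the full $V_{pp}$ in its single phase. Current-mode protocols
use only charge-balanced shapes: the symmetric biphasic pulse and a
triphasic pulse with per-phase amplitude ratio 2:3:1
(anodic–cathodic–anodic, $\tfrac23 A - A + \tfrac13 A = 0$), with the
nominal amplitude $A$ anchored on the middle cathodic phase. Phase
durations span 10–200 µs; pulses are synthesized at 1 MHz because a
20 µs phase is sub-sample on the 20 kHz recording grid.

Charge is accounted per phase in two schemes:

* current mode: $q = I\,t$ — exact, impedance-independent;
* voltage mode: $q = C_{dl}\,\Delta v$, the charge moved onto the
  double-layer capacitance by the voltage excursion.

$\Delta v$ for a biphasic pulse is ambiguous between $V_{pp}$ and
$V_{pp}/2$; the package defaults to the per-phase excursion $V_{pp}/2$
(each phase moves the interface that far from rest) and exposes the
alternative through `voltage_excursion(convention = "vpp")`.

```{r}
charge_per_phase_current(100, 18)                 # pC, the minimal effective pulse
charge_density(charge_per_phase_current(42, 20))  # pC/um^2 on a 5 x 9 um electrode
min_successes_for_efficiency(30, 0.9)             # the 90%-of-30 criterion
```

Protocols repeat every condition 30 times at 1 Hz under a single seeded
global permutation — not per-condition blocks — so that repeats of one
condition are scattered across the protocol (blocked repetition risks
plasticity confounds).

## The electrode-interface model

The interface is a charge-transfer resistance $R_{ct}$ in parallel with
a double-layer capacitance $C_{dl}$, read out through a channel of
constant resistive input impedance $Z_{in}$. Under a current step $I$
the readout voltage is

$$V(t) \;=\; \frac{I\,R_{ct}\left(1 - e^{-t/(R_{ct}C_{dl})}\right)}
{1 + \dfrac{R_{ct}}{Z_{in}}\left(1 - e^{-t/(R_{ct}C_{dl})}\right)}.$$

This is the only reading of the model with the three physically
required limits, all of which are property-tested: $V(0)=0$, initial
slope $I/C_{dl}$ (the step initially charges the capacitor), and the
resistive-divider asymptote $I R_{ct}/(1+R_{ct}/Z_{in})$. The
exponential underflows cleanly for $t \gg R_{ct}C_{dl}$, so no special
casing is needed.

`fit_transient()` recovers $(R_{ct}, C_{dl})$ from the positive phase of
a recorded transient by Levenberg–Marquardt least squares on log-scale
parameters, with $Z_{in}$ held fixed, the readout gain divided out
first, and a coarse log-grid multi-start (8 × 7 points over
$10^5$–$10^{8.5}$ Ω × $10^{-11}$–$10^{-8}$ F) so the result does not
depend on the initial guess. Convergence is reported explicitly; flat
traces are rejected. $Z_{in}$ is not published for this chip family; the
default is 50 MΩ resistive, and in round-trip work its exact value
cancels because generation and fitting share it.

```{r}
circ <- electrode_circuit(R_ct = 10e6, C_dl = 1.44e-9, Z_in = 50e6)
rec <- forward_transient(circ, 560e-9, 2.5e-3, gain = 2,
                         noise_rms_V = 10e-6, seed = 1)
fit_transient(rec)
```

With the stimulus parameters used for impedance characterization
(Pt-black: 560 nA, 2.5 ms per phase; bright Pt: 140 nA, 1 ms; gain 2;
10 µV rms noise) the fit recovers the generating capacitance to a few
parts in $10^4$, far inside the ±0.15 nF (Pt-black) and ±0.0138 nF
(bright Pt) spreads observed across electrode populations.

## What the synthetic recordings emulate — and what they do not

A `synthetic_neuron` bundles the features recordings depend on:

* **Footprint.** EAP trough amplitude is maximal at the axon initial
  segment (AIS) — the spike-initiation zone, the most
  stimulation-sensitive compartment, and the experimental
  electrode-selection target — and decays as $e^{-d/\lambda}$ with
  $\lambda = 25$ µm, spanning a few electrodes at 17.5 µm pitch. Real
  footprints are anisotropic along the axon; an isotropic exponential is
  the minimal model with the right argmax and scale.
* **Template.** A 1.2 ms biphasic spike (sharp negative trough, smaller
  positive overshoot), peak 100–300 µV at the AIS electrode; shape
  configurable.
* **Activation model.** The response to a pulse of charge $q$ is
  Bernoulli with
  $p(q) = p_{\max} / \left(1 + e^{-(q - q_{50})/s}\right)$.
  This logistic link is *invented*: experiments report only empirical
  activation curves, and the sigmoid is the minimal monotone model
  reproducing them. $q_{50}$, slope $s$ and $p_{\max}$ are exposed in
  every generator.
* **Latency.** Evoked troughs are placed at a truncated-Gaussian latency
  (mean 0.8 ms, SD 0.15 ms) inside the 1.5 ms evoked window. The lower
  truncation is 0.4 ms rather than 0: a latency inside the
  post-stimulus blanking interval would be undetectable by
  construction, and the detector/ground-truth agreement guarantees
  below assume responses land in the searchable part of the window.

Recording noise is white Gaussian at 2.4 µV rms on the 20 kHz grid.
The hardware's 300 Hz–10 kHz band-pass is *not* modeled; one
consequence is handled in the detector (see below). Traces clip at
±3 mV, a stand-in for amplifier saturation (the true rail is
unpublished).

**Artifacts.** The stimulation artifact is the interface response to
the pulse — integrated exactly per sample in current mode, the
commanded voltage in voltage mode — scaled spatially by
$e^{-d/\lambda_{art}}$ ($\lambda_{art} = 100$ µm), rendered onto the
recording grid (bins overlapping the pulse hold the signed extremum, so
sub-sample 20 µs pulses remain visible), and clipped. After the pulse
the trace relaxes with a fast recovery constant (15 µs); voltage-mode
artifacts additionally carry a positive baseline offset (50 µV per
100 mV drive, decaying with 0.5 ms) that evoked responses ride on —
which is why voltage-mode detection is intrinsically harder, as in the
experiments. None of these constants is published; all are explicit
placeholders in the configuration, chosen so that the qualitative
findings (current-mode artifacts shorter and more benign than
voltage-mode ones) hold.

Passing tests therefore demonstrate correctness of the *pipeline* under
a plausible data model — threshold logic, counting, determinism, charge
accounting — not fidelity to any particular culture's biophysics.

## Detection

Spontaneous spikes are negative threshold crossings at $-4.5\,\sigma$ of
the noise with a 1 ms refractory merge; evoked responses are crossings
at $-4\,\sigma$ inside $(t_{stim} + \text{blanking},\, t_{stim} +
1.5\,\text{ms}]$. Design points:

* **Two-sample crossing rule.** A crossing must hold for 2 consecutive
  samples. With *unfiltered* white noise, a single-sample rule fires
  $\approx 4$ times per minute at $4.5\sigma$ (Gaussian tail × 1.2 M
  samples), which would contaminate every efficiency table; band-pass
  filtering, which suppresses such single-sample excursions in real
  systems, is out of scope, and the two-sample rule is its minimal
  surrogate. Recall for ≥6 σ spikes is unaffected (several consecutive
  template samples sit below threshold at 20 kHz).
* **Blanking** is pulse duration + 100 µs (current) or + 300 µs
  (voltage), matching the visibly faster current-mode recovery;
  configurable.
* **Noise** is estimated on the stimulus-free lead-in segment, never
  inside stimulation epochs; `mad` is available for spike-contaminated
  segments.
* **Indeterminate pulses.** If saturated samples cover more than half
  of the evoked window the pulse is classed indeterminate — the
  automated analogue of artifact-covered responses that required manual
  inspection. By default these are excluded from the efficiency
  denominator; `count_indeterminate_as_failure = TRUE` selects the
  other convention, since how such pulses entered the 30-pulse
  denominators experimentally is not stated.
* **Polarity.** Only negative-going detection is implemented. Responses
  shifted above threshold by voltage-mode baseline offsets are missed,
  deliberately: the experimental workaround was visual inspection, and
  the indeterminate flag replaces it.

The activation threshold for a (shape, duration) is the smallest tested
amplitude whose success count reaches
`min_successes_for_efficiency(n, 0.9)` — 27 of 30 — and a series of
thresholds across recording days is normalized to its maximum for
cross-neuron comparison.

## Field simulation

`solve_laplace()` solves $\nabla \cdot (\sigma \nabla V) = 0$ (uniform
$\sigma = 0.7$ S/m, so plain Laplace) over an electrolyte block above
the electrode plane, with Dirichlet values on driven/grounded patches
and the four grounded reference strips, and insulating
zero-normal-derivative closure elsewhere, using red-black SOR in
compiled code (near-optimal relaxation factor, relative update
tolerance $10^{-8}$, deterministic). $|E| = \sqrt{E_x^2+E_y^2+E_z^2}$
comes from central differences. Design points:

* **Floating electrodes are absent.** Unused electrodes have no defined
  potential; modeling true floating conductors (equipotential, zero net
  current) is out of scope, so they are treated as part of the
  insulating plane.
* **Static snapshots.** The biphasic ±100 mV drive is represented by
  its +100 mV phase; by linearity the negative phase is the sign flip,
  and no time stepping is needed in the quasi-static regime.
* **No interface impedance in the solver.** Patches are ideal Dirichlet
  surfaces, consistent with stationary conduction modeling.
* **Convergence.** Raw probe voltages converge first order in the grid
  spacing because the discrete Dirichlet patch (default 2.5 µm spacing,
  2 × 4 nodes per 5 × 9 µm patch) effectively grows by half a cell;
  refinement tests therefore assert that successive halvings shrink the
  change and that *comparative* quantities — the between-scenario field
  ratios on which the configuration comparison rests — are converged to
  better than 2 %.

The three scenarios (single electrode vs distant reference,
opposite-sign pair, grounded neighbor) reproduce the qualitative
experimental picture: the voltage drop near the stimulation site is
comparable in all configurations (so no scenario is a free win in
stimulation efficacy), the opposite-sign pair increases the field
between the electrodes while decreasing the voltage there, and it
shortens the lateral artifact extent.

## Problem sizes and reproducibility

Every stochastic step takes an explicit seed and restores the caller's
RNG state; identical seeds give bit-identical blocks, ground truth and
result tables, and `run_end_to_end()` manifests carry a hash of the
scientific configuration (the output path is excluded). The shipped
analyses and tests run at desk scale by choice: sessions use 2 × 2 to
3 × 3 electrode blocks around one neuron with 1–16 conditions × 30
repetitions at 1 Hz (protocol length 1–8 minutes of simulated
recording), detector/ground-truth agreement is checked over 100 seeded
sessions, impedance recovery over 20–100 noisy replicates, and field
solutions use reduced blocks (120–300 µm) at 2.5 µm spacing with the
full 500 × 500 × 100 µm domain available through `build_domain()`
defaults. Per-neuron in-vitro quantities (which neuron fires at which
amplitude on which day) are not reproducible from a synthetic model and
are deliberately out of scope; the package validates the machinery that
measures them.

## Known limitations

* No biophysical (cable / Hodgkin–Huxley) neuron model, no axonal
  propagation, no overlapping-spike scenarios, no plasticity.
* No Warburg/constant-phase elements or Faradaic electrochemistry in
  the interface model; no spreading resistance term.
* White (unfiltered) noise; the recording band-pass is approximated
  only through the detector's two-sample rule.
* Artifact amplitude and decay constants are synthetic placeholders.
* Field solver: no double-layer impedance at the patches, no true
  floating conductors, no time domain.
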