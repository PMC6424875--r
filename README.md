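# meastim

Simulation and analysis of single-neuron electrical stimulation on
CMOS high-density microelectrode arrays (HD-MEAs).

HD-MEAs carry thousands of small platinum electrodes (5 × 9 µm at
17.5 µm pitch) that both record extracellular action potentials (EAPs)
at 20 kSamples/s and inject stimulation pulses. Working at this scale
raises questions this package makes computable for electrophysiologists
and neural-interface engineers:

* Which waveform, duration and amplitude evoke a spike reliably, and
  how much charge does that take? Charge is `q = I·t` per phase in
  current mode and `q = C_dl·Δv` in voltage mode, where `C_dl` is the
  double-layer capacitance of the electrode–electrolyte interface.
* What is `C_dl`? The interface is modeled as a charge-transfer
  resistance `R_ct` in parallel with `C_dl`, read out through a channel
  of input impedance `Z_in`; under a current step

  `V(t) = I·R_ct·(1 − e^(−t/(R_ct·C_dl))) / (1 + (R_ct/Z_in)·(1 − e^(−t/(R_ct·C_dl))))`

  and a nonlinear least-squares fit of the positive pulse phase
  recovers `R_ct` and `C_dl`.
* How are evoked spikes counted next to the stimulation artifact?
  Spontaneous spikes are detected at −4.5 × the noise SD; evoked
  responses at −4 × SD inside a 1.5 ms post-stimulus window (with
  blanking and saturation handling). The activation threshold is the
  smallest amplitude evoking spikes in ≥ 90 % of 30 repetitions
  (≥ 27/30).
* Do multi-electrode configurations help? A finite-difference solver
  for the quasi-static potential `∇·(σ∇V) = 0` over the electrolyte
  compares single-electrode, opposite-sign-pair and grounded-neighbor
  stimulation, including the field magnitude `|E| = √(Ex²+Ey²+Ez²)`.

Because no recordings ship with the package, a seeded synthetic-data
module generates ground-truth-annotated multi-electrode recordings
(EAP footprints decaying from the axon initial segment, stimulation
artifacts in both modes, logistic Bernoulli evoked responses) against
which the whole detection pipeline is validated.

## Worked example

Fit the interface model to a simulated Pt-black transient (560 nA,
2.5 ms per phase, gain 2, 10 µV rms noise), then recover activation
thresholds from a synthetic stimulation session:

```r
library(meastim)

circ <- electrode_circuit(R_ct = 10e6, C_dl = 1.44e-9, Z_in = 50e6)
rec  <- forward_transient(circ, 560e-9, 2.5e-3, gain = 2,
                          noise_rms_V = 10e-6, seed = 1)
fit_transient(rec)
#> <fit_result> R_ct = 10 MOhm, C_dl = 1.44 nF, residual 4.09e-06 V rms, converged (6 it.)

geometry <- array_geometry(3, 3)
neuron   <- synthetic_neuron(c(17.5, 17.5), q50_pC = 2.0, slope_pC = 0.15)
conds    <- current_protocol_conditions(durations_us = 20)   # 42-189 nA, 2 waveforms
protocol <- randomize_protocol(conds, repetitions = 30, rate = 1, seed = 101)
session  <- simulate_session(protocol, neuron, geometry, circ, seed = 102)
activation_threshold(efficiency_table(session), efficiency = 0.9)
#> <activation_curve> 90% criterion
#>     mode                            shape duration_us threshold threshold_charge_pC reached
#>  current         biphasic_anodic_cathodic          20       126                2.52    TRUE
#>  current triphasic_anodic_cathodic_anodic          20       126                2.52    TRUE
```

The fit returns the generating capacitance (1.44 nF); the session's
90 % threshold lands on 126 nA × 20 µs = 2.52 pC, the first grid point
whose charge clears the neuron's half-activation charge of 2.0 pC.

## Analysis workflow

Numbered drivers under `analysis/` run the full set of analyses and
write tables under `results/`:

| script | what it computes |
| --- | --- |
| `01_waveforms_and_charge.R` | condition grids, charge balance, per-condition charge and charge density |
| `02_impedance_fit.R` | Pt-black and bright-Pt capacitance recovery, divider probe, drift |
| `03_activation_curves.R` | synthetic session → efficiency table → 90 % thresholds |
| `04_development_series.R` | thresholds across recording days with a moving, developing neuron |
| `05_field_simulation.R` | three-scenario field comparison with probe tables |
| `06_pipeline_demo.R` | reproducible end-to-end run with HDF5 + CSV + manifest |

Each is a thin narrative wrapper over package functions, e.g.
`Rscript analysis/02_impedance_fit.R`.

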