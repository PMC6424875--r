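#' Stimulation waveform shapes
#'
#' Shapes available on the stimulation units. Monophasic shapes are
#' voltage-mode only (a monophasic current pulse would not be charge
#' balanced); the triphasic shape is current-mode only.
#'
#' @format Character vector of shape names.
#' @keywords internal
WAVEFORM_SHAPES <- c(
  "monophasic_anodic", "monophasic_cathodic",
  "biphasic_anodic_cathodic", "biphasic_cathodic_anodic",
  "triphasic_anodic_cathodic_anodic"
)

shape_legal_for_mode <- function(mode, shape) {
  if (mode == "current") {
    shape %in% c("biphasic_anodic_cathodic", "biphasic_cathodic_anodic",
                 "triphasic_anodic_cathodic_anodic")
  } else {
    shape %in% c("monophasic_anodic", "monophasic_cathodic",
                 "biphasic_anodic_cathodic", "biphasic_cathodic_anodic")
  }
}

# Per-phase scale factors relative to the nominal amplitude, in temporal
# order. Anodic = positive excursion, cathodic = negative. Voltage
# amplitudes are peak-to-peak, so biphasic voltage phases swing +/- Vpp/2;
# monophasic voltage pulses use the full Vpp as the single-phase amplitude.
# Current amplitudes are per-phase peaks. The triphasic shape uses the
# 2:3:1 charge-balanced ratio with the nominal amplitude anchored, by
# default, on the middle (cathodic) phase.
phase_scales <- function(mode, shape, triphasic_anchor = c("cathodic", "largest")) {
  triphasic_anchor <- match.arg(triphasic_anchor)
  half <- if (mode == "voltage") 0.5 else 1
  switch(shape,
    monophasic_anodic       = +1,
    monophasic_cathodic     = -1,
    biphasic_anodic_cathodic = c(+half, -half),
    biphasic_cathodic_anodic = c(-half, +half),
    triphasic_anodic_cathodic_anodic = {
      s <- c(+2 / 3, -1, +1 / 3)
      if (triphasic_anchor == "largest") s else s  # cathodic phase is the largest
    },
    stop_mea("unknown shape '%s'", shape)
  )
}

#' Build a sampled stimulation waveform
#'
#' Constructs a rectangular stimulation pulse as used on HD-MEA stimulation
#' units: monophasic or biphasic in voltage mode, charge-balanced biphasic
#' or triphasic (amplitude ratio 2:3:1, anodic-cathodic-anodic) in current
#' mode. All phases share one duration; phase boundaries fall exactly on
#' sample boundaries of the synthesis grid.
#'
#' @param mode `"voltage"` or `"current"`.
#' @param shape One of `r paste0('\x60', WAVEFORM_SHAPES, '\x60', collapse=", ")`.
#' @param phase_duration_us Duration of each phase in microseconds (> 0).
#' @param amplitude Nominal amplitude: mV peak-to-peak in voltage mode, nA
#'   per-phase peak in current mode (for the triphasic shape, the peak of
#'   the middle cathodic phase). Must be >= 0.
#' @param sample_rate Synthesis sampling rate in Hz (default 1 MHz; high
#'   enough that 10 us phases are well resolved; decimation to the 20 kHz
#'   recording grid happens in the recording simulator).
#' @return An object of class `stim_waveform` with fields `mode`, `shape`,
#'   `phase_duration_us`, `amplitude`, `sample_rate`, `samples` (native
#'   units: mV or nA) and `n_phases`.
#' @examples
#' w <- build_waveform("current", "biphasic_anodic_cathodic", 20, 100)
#' net_charge(w)  # 0 pC: charge balanced
#' @export
build_waveform <- function(mode = c("voltage", "current"), shape,
                           phase_duration_us, amplitude,
                           sample_rate = 1e6) {
  mode <- match.arg(mode)
  shape <- match.arg(shape, WAVEFORM_SHAPES)
  if (!shape_legal_for_mode(mode, shape)) {
    stop_mea("shape '%s' is not legal in %s mode (monophasic: voltage only; triphasic: current only)",
             shape, mode)
  }
  if (!is.numeric(phase_duration_us) || phase_duration_us <= 0) {
    stop_mea("phase_duration_us must be > 0")
  }
  if (!is.numeric(amplitude) || amplitude < 0) stop_mea("amplitude must be >= 0")
  n_per_phase <- round(phase_duration_us * 1e-6 * sample_rate)
  if (n_per_phase < 2) {
    stop_mea("phase of %g us spans only %d sample(s) at %g Hz; need >= 2 samples per phase",
             phase_duration_us, n_per_phase, sample_rate)
  }
  scales <- phase_scales(mode, shape)
  samples <- rep(scales * amplitude, each = n_per_phase)
  structure(
    list(mode = mode, shape = shape,
         phase_duration_us = phase_duration_us, amplitude = amplitude,
         sample_rate = sample_rate, samples = samples,
         n_phases = length(scales)),
    class = "stim_waveform"
  )
}

#' @export
print.stim_waveform <- function(x, ...) {
  unit <- if (x$mode == "voltage") "mV pp" else "nA"
  cat(sprintf("<stim_waveform> %s %s: %g us/phase, %g %s, %d samples @ %g Hz\n",
              x$mode, x$shape, x$phase_duration_us, x$amplitude, unit,
              length(x$samples), x$sample_rate))
  invisible(x)
}

#' Net injected charge of a current-mode waveform
#'
#' Exact sum of the sampled currents times the sample period. Charge-
#' balanced shapes (biphasic, triphasic 2:3:1) return zero up to one
#' sample-quantization unit.
#'
#' @param w A `stim_waveform` in current mode.
#' @return Net charge in pC.
#' @export
net_charge <- function(w) {
  stopifnot(inherits(w, "stim_waveform"))
  if (w$mode != "current") {
    stop_mea("net charge is only defined for current-mode waveforms (voltage-mode charge requires the electrode model; see charge_voltage_mode)")
  }
  dt_us <- 1e6 / w$sample_rate
  sum(w$samples) * dt_us / 1000  # nA * us -> 1e-3 pC
}

#' Charge per phase of a current pulse, q = I * t
#'
#' The current-mode charge accounting used to compare stimulation
#' modalities: the per-phase charge is the product of the applied current
#' and the phase duration.
#'
#' @param I_nA Phase current in nA (>= 0).
#' @param t_us Phase duration in microseconds (> 0).
#' @return Charge in pC.
#' @examples
#' charge_per_phase_current(100, 18)  # 1.8 pC
#' @export
charge_per_phase_current <- function(I_nA, t_us) {
  if (any(I_nA < 0)) stop_mea("I_nA must be >= 0")
  if (any(t_us <= 0)) stop_mea("t_us must be > 0")
  I_nA * t_us / 1000
}

#' Charge delivered by a voltage pulse, q = C * delta-v
#'
#' Voltage-mode charge accounting through the double-layer capacitance:
#' the charge moved onto the interface is the capacitance times the
#' per-phase voltage excursion.
#'
#' @param C_dl_nF Double-layer capacitance in nF (> 0).
#' @param delta_v_mV Per-phase voltage excursion in mV (>= 0). See
#'   [voltage_excursion()] for the conventions mapping a peak-to-peak
#'   amplitude to an excursion.
#' @return Charge in pC.
#' @export
charge_voltage_mode <- function(C_dl_nF, delta_v_mV) {
  if (any(C_dl_nF <= 0)) stop_mea("C_dl_nF must be > 0")
  if (any(delta_v_mV < 0)) stop_mea("delta_v_mV must be >= 0")
  C_dl_nF * delta_v_mV
}

#' Per-phase voltage excursion of a waveform amplitude
#'
#' Maps a peak-to-peak voltage amplitude to the per-phase excursion used in
#' `q = C * delta-v`. For a biphasic pulse of amplitude Vpp each phase
#' swings Vpp/2 away from baseline, which is the default convention
#' (`"half_vpp"`); `"vpp"` uses the full peak-to-peak swing instead. For
#' monophasic shapes the single phase carries the full amplitude under
#' either convention.
#'
#' @param amplitude_mVpp Peak-to-peak amplitude in mV.
#' @param shape Waveform shape (see [build_waveform()]).
#' @param convention `"half_vpp"` (default) or `"vpp"`.
#' @return Excursion in mV.
#' @export
voltage_excursion <- function(amplitude_mVpp, shape = "biphasic_anodic_cathodic",
                              convention = c("half_vpp", "vpp")) {
  convention <- match.arg(convention)
  shape <- match.arg(shape, WAVEFORM_SHAPES)
  if (grepl("^monophasic", shape)) return(amplitude_mVpp)
  if (convention == "half_vpp") amplitude_mVpp / 2 else amplitude_mVpp
}

#' Charge density over the electrode area
#'
#' @param q_pC Charge in pC.
#' @param electrode_area_um2 Geometric electrode area in square micrometers
#'   (default the 5 x 9 um HD-MEA electrode).
#' @return Charge density in pC/um^2.
#' @examples
#' charge_density(charge_per_phase_current(42, 20))  # ~0.019 pC/um^2
#' @export
charge_density <- function(q_pC, electrode_area_um2 = 5 * 9) {
  if (any(electrode_area_um2 <= 0)) stop_mea("electrode_area_um2 must be > 0")
  q_pC / electrode_area_um2
}

#' Minimal success count reaching an efficiency level
#'
#' Smallest integer k such that k/n >= efficiency; e.g. 27 of 30
#' repetitions for the 90% criterion used to define activation thresholds.
#'
#' @param n Number of repetitions (>= 1).
#' @param efficiency Target success fraction in (0, 1].
#' @return Integer count.
#' @examples
#' min_successes_for_efficiency(30, 0.9)  # 27
#' @export
min_successes_for_efficiency <- function(n, efficiency) {
  if (!is.numeric(n) || n < 1) stop_mea("n must be >= 1")
  if (!is.numeric(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop_mea("efficiency must be in (0, 1]")
  }
  n <- as.integer(round(n))
  k <- 0:n
  k[which(k / n >= efficiency)[1]]
}
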