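#' Electrode-electrolyte equivalent circuit
#'
#' The interface is modeled as a charge-transfer resistance `R_ct` in
#' parallel with a double-layer capacitance `C_dl`, read out through a
#' recording channel of constant resistive input impedance `Z_in`.
#'
#' @param R_ct Charge-transfer resistance in Ohm (> 0).
#' @param C_dl Double-layer capacitance in Farad; sanity band 1 pF - 1 uF.
#' @param Z_in Recording-channel input impedance in Ohm (default 50 MOhm,
#'   resistive; the chip value is not published).
#' @return Object of class `electrode_circuit`.
#' @export
electrode_circuit <- function(R_ct = 10e6, C_dl = 1e-9, Z_in = 50e6) {
  if (R_ct <= 0 || C_dl <= 0 || Z_in <= 0) stop_mea("circuit parameters must be > 0")
  if (C_dl < 1e-12 || C_dl > 1e-6) {
    stop_mea("C_dl = %.3g F outside the sanity band [1 pF, 1 uF]", C_dl)
  }
  structure(list(R_ct = R_ct, C_dl = C_dl, Z_in = Z_in),
            class = "electrode_circuit")
}

#' @export
print.electrode_circuit <- function(x, ...) {
  cat(sprintf("<electrode_circuit> R_ct = %.3g MOhm, C_dl = %.4g nF, Z_in = %.3g MOhm\n",
              x$R_ct / 1e6, x$C_dl * 1e9, x$Z_in / 1e6))
  invisible(x)
}

# Closed-form electrode voltage under a current step, derived from the
# interface model with the recording channel in parallel:
#   V(t) = I R_ct (1 - e^(-t/(R_ct C_dl))) / (1 + (R_ct/Z_in)(1 - e^(-t/(R_ct C_dl))))
# This is the reading with V(0) = 0, initial slope I/C_dl, and the
# resistive-divider asymptote I R_ct / (1 + R_ct/Z_in). exp() underflows
# cleanly to 0 for t >> R_ct C_dl, so no special casing is needed.
transient_voltage <- function(t, I_stim, R_ct, C_dl, Z_in) {
  g <- 1 - exp(-t / (R_ct * C_dl))
  I_stim * R_ct * g / (1 + (R_ct / Z_in) * g)
}

#' Forward transient of the electrode model under a current step
#'
#' Voltage across the interface while a constant current `I_stim` is
#' injected, sampled on a uniform grid. Monotonically non-decreasing from
#' V(0) = 0 towards the divider asymptote `I R_ct / (1 + R_ct/Z_in)`, with
#' initial slope `I / C_dl`.
#'
#' @param circuit An [electrode_circuit()].
#' @param I_stim Applied current in A.
#' @param duration Duration of the step in seconds.
#' @param sample_rate Sampling rate in Hz (default the 20 kHz recording
#'   grid).
#' @param gain Readout gain applied multiplicatively to the recorded
#'   voltage (default 1; impedance characterization used gain 2).
#' @param noise_rms_V Gaussian noise added to the recorded trace, in V rms
#'   (default 0).
#' @param seed Seed for the noise draw (required if `noise_rms_V > 0`).
#' @return Object of class `transient_recording`: list(time, voltage,
#'   I_stim, phase_duration, gain), with `time[1] = 0`.
#' @export
forward_transient <- function(circuit, I_stim, duration,
                              sample_rate = 20000, gain = 1,
                              noise_rms_V = 0, seed = NULL) {
  stopifnot(inherits(circuit, "electrode_circuit"))
  if (duration <= 0) stop_mea("duration must be > 0")
  t <- seq(0, duration, by = 1 / sample_rate)
  v <- transient_voltage(t, I_stim, circuit$R_ct, circuit$C_dl, circuit$Z_in)
  v <- v * gain
  if (noise_rms_V > 0) {
    if (is.null(seed)) stop_mea("seed required when noise_rms_V > 0")
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_rms_V))
  }
  structure(list(time = t, voltage = v, I_stim = I_stim,
                 phase_duration = duration, gain = gain),
            class = "transient_recording")
}

#' Fit the electrode model to a recorded transient
#'
#' Nonlinear least-squares recovery of `R_ct` and `C_dl` from the positive
#' (first) phase of a current-step readout, with `Z_in` held fixed. The
#' readout gain is divided out before fitting. Initialization is taken
#' from `init` when given; in addition a coarse log-spaced multi-start
#' grid is evaluated and the best starting residual is used, which removes
#' sensitivity to the initial guess. Fitting uses Levenberg-Marquardt
#' least squares (relative step tolerance 1e-10, at most 500 iterations);
#' non-convergence is reported in the result, never silently.
#'
#' @param rec A `transient_recording` restricted to the positive phase
#'   (>= 10 samples).
#' @param Z_in Input impedance in Ohm, held fixed during the fit.
#' @param init Optional `c(R_ct, C_dl)` initial values (Ohm, F); defaults
#'   to literature-scale 10 MOhm / 1 nF and is augmented by the
#'   multi-start grid.
#' @param multistart If `TRUE` (default) evaluate a log-grid of starting
#'   points and refine from the best.
#' @return Object of class `fit_result`: list(R_ct_hat, C_dl_hat,
#'   residual_rms, converged, n_iterations).
#' @export
fit_transient <- function(rec, Z_in = 50e6, init = c(R_ct = 10e6, C_dl = 1e-9),
                          multistart = TRUE) {
  stopifnot(inherits(rec, "transient_recording"))
  t <- rec$time
  v <- rec$voltage / rec$gain
  if (length(t) < 10) stop_mea("need >= 10 samples of the positive phase to fit")
  if (stats::sd(v) == 0 || max(abs(v)) == 0) {
    stop_mea("flat or zero trace: transient carries no information about (R_ct, C_dl)")
  }
  I <- rec$I_stim

  # parameters are fitted on log scale: both span decades and must stay > 0
  ssr <- function(p) {
    r <- v - transient_voltage(t, I, exp(p[1]), exp(p[2]), Z_in)
    sum(r * r)
  }
  starts <- list(log(unname(init)))
  if (multistart) {
    grid <- expand.grid(R = log(10^seq(5, 8.5, by = 0.5)),
                        C = log(10^seq(-11, -8, by = 0.5)))
    sse <- vapply(seq_len(nrow(grid)),
                  function(i) ssr(c(grid$R[i], grid$C[i])), 0)
    starts <- c(starts, list(c(grid$R[which.min(sse)], grid$C[which.min(sse)])))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) v - transient_voltage(t, I, exp(p[1]), exp(p[2]), Z_in),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10,
                                             maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop_mea("transient fit failed from every starting point")
  est <- exp(best$par)
  converged <- best$info %in% 1:4
  structure(
    list(R_ct_hat = est[1], C_dl_hat = est[2],
         residual_rms = sqrt(best$deviance / length(v)),
         converged = converged, n_iterations = best$niter),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> R_ct = %.4g MOhm, C_dl = %.4g nF, residual %.3g V rms, %s (%d it.)\n",
              x$R_ct_hat / 1e6, x$C_dl_hat * 1e9, x$residual_rms,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Recorded amplitude of the sine-wave impedance probe
#'
#' Amplitude recorded on a channel when a sine wave is applied to the bath
#' reference: the electrode impedance `Z_el(w) = R_ct / (1 + j w R_ct
#' C_dl)` forms a divider with the resistive input impedance, so the
#' recorded amplitude is `V_applied * |Z_in| / |Z_el + Z_in|`. Used to
#' assess impedance homogeneity across electrode populations (the probe
#' used 1 kHz, 50 mV peak-to-peak).
#'
#' @param circuit An [electrode_circuit()].
#' @param f Frequency in Hz (> 0).
#' @param V_applied_mVpp Applied amplitude in mV peak-to-peak (default 50).
#' @return Recorded amplitude in mV peak-to-peak.
#' @export
sine_divider_amplitude <- function(circuit, f = 1000, V_applied_mVpp = 50) {
  stopifnot(inherits(circuit, "electrode_circuit"))
  if (f <= 0) stop_mea("f must be > 0")
  w <- 2 * pi * f
  Z_el <- circuit$R_ct / (1 + 1i * w * circuit$R_ct * circuit$C_dl)
  V_applied_mVpp * Mod(circuit$Z_in) / Mod(Z_el + circuit$Z_in)
}

#' Capacitance drift as a percentage of a reference value
#'
#' Post-experiment drift check: e.g. a 0.07 nF change against the 1.44 nF
#' Pt-black mean is about 5%.
#'
#' @param delta_C_nF Observed change in nF.
#' @param reference_C_nF Reference capacitance in nF (> 0).
#' @return Drift in percent.
#' @export
impedance_drift_percent <- function(delta_C_nF, reference_C_nF) {
  if (any(reference_C_nF <= 0)) stop_mea("reference_C_nF must be > 0")
  100 * delta_C_nF / reference_C_nF
}
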