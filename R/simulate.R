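new_recording_block <- function(geometry, sample_rate, traces, noise_rms_uV,
                                saturation_limit_uV, seed) {
  structure(
    list(geometry = geometry, sample_rate = sample_rate, traces = traces,
         noise_rms_uV = noise_rms_uV, saturation_limit_uV = saturation_limit_uV,
         seed = seed),
    class = "recording_block"
  )
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf("<recording_block> %d electrodes x %d samples @ %g Hz (%.1f s), noise %g uV rms, clip +/-%g uV\n",
              nrow(x$traces), ncol(x$traces), x$sample_rate,
              ncol(x$traces) / x$sample_rate, x$noise_rms_uV,
              x$saturation_limit_uV))
  invisible(x)
}

clip_traces <- function(traces, limit_uV) {
  traces[traces > limit_uV] <- limit_uV
  traces[traces < -limit_uV] <- -limit_uV
  traces
}

# Column indices and template subset for inserting a template whose
# `align_index`-th sample lands on `at_sample`; parts outside the block
# are dropped. Subassignment is done at the call site so the trace matrix
# is modified in place (passing it through a function would copy it).
insert_span <- function(n_cols, template, align_index, at_sample) {
  start <- at_sample - align_index + 1
  idx <- seq.int(start, start + length(template) - 1)
  keep <- idx >= 1 & idx <= n_cols
  list(cols = idx[keep], values = template[keep])
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a spontaneous-activity recording
#'
#' Seeded multi-electrode recording of one neuron firing as a Poisson
#' process: each spike inserts the EAP template on every electrode,
#' scaled by the neuron's spatial footprint, on top of white Gaussian
#' noise at the recording-noise level (2.4 uV rms by default). Traces are
#' clipped at the amplifier saturation limit.
#'
#' @param neuron A [synthetic_neuron()].
#' @param geometry An [array_geometry()].
#' @param duration_s Recording length in seconds.
#' @param firing_rate_hz Mean firing rate (Poisson).
#' @param noise_rms_uV Recording noise in uV rms (default 2.4).
#' @param sample_rate Hz (default 20000).
#' @param saturation_limit_mV Amplifier clipping limit (default +/-3 mV).
#' @param seed Integer seed; identical seeds give identical blocks.
#' @return List with `block` (a `recording_block`) and `spike_times_s`
#'   (ground-truth trough times).
#' @export
simulate_spontaneous <- function(neuron, geometry, duration_s = 60,
                                 firing_rate_hz = 2, noise_rms_uV = 2.4,
                                 sample_rate = 20000, saturation_limit_mV = 3,
                                 seed = 1) {
  if (duration_s * firing_rate_hz < 1) {
    stop_mea("duration x rate = %.3g < 1 expected spike", duration_s * firing_rate_hz)
  }
  fp <- eap_footprint(neuron, geometry)
  tmpl <- eap_template(sample_rate)
  n_el <- n_electrodes(geometry)
  n_s <- round(duration_s * sample_rate)
  margin <- length(tmpl$samples) / sample_rate
  with_seed(seed, {
    n_spk <- stats::rpois(1, duration_s * firing_rate_hz)
    times <- sort(stats::runif(n_spk, margin, duration_s - margin))
    traces <- matrix(stats::rnorm(n_el * n_s, 0, noise_rms_uV), n_el, n_s)
    for (tt in times) {
      sp <- insert_span(n_s, tmpl$samples, tmpl$trough_index,
                        round(tt * sample_rate) + 1)
      traces[, sp$cols] <- traces[, sp$cols] + outer(fp, sp$values)
    }
    traces <- clip_traces(traces, saturation_limit_mV * 1000)
    list(block = new_recording_block(geometry, sample_rate, traces,
                                     noise_rms_uV, saturation_limit_mV * 1000,
                                     seed),
         spike_times_s = times)
  })
}

# Interface voltage (uV) on the waveform's fine synthesis grid plus the
# analytic post-pulse recovery, before spatial scaling and clipping.
# Current mode integrates C_dl dV/dt = I(t) - V/R_ct - V/Z_in exactly per
# sample (piecewise-constant drive); voltage mode applies the commanded
# voltage directly across the interface. After the pulse the recorded
# artifact relaxes with a fast amplifier-recovery constant `tau_rec_us`,
# plus - in voltage mode only - a slower positive baseline-offset term
# that emulates the baseline shift evoked responses ride on. Neither time
# constant is published; both are synthetic placeholders and configurable.
artifact_components <- function(mode, waveform, circuit,
                                tau_rec_us, baseline_shift_uV_per_100mV,
                                tau_base_ms) {
  dt <- 1 / waveform$sample_rate
  if (mode == "current") {
    I_A <- waveform$samples * 1e-9
    Req <- 1 / (1 / circuit$R_ct + 1 / circuit$Z_in)
    tau <- circuit$C_dl * Req
    a <- exp(-dt / tau)
    v <- numeric(length(I_A))
    prev <- 0
    for (k in seq_along(I_A)) {
      prev <- prev * a + I_A[k] * Req * (1 - a)
      v[k] <- prev
    }
    fine_uV <- v * 1e6
    baseline_uV <- 0
  } else {
    fine_uV <- waveform$samples * 1000  # mV -> uV
    baseline_uV <- baseline_shift_uV_per_100mV * waveform$amplitude / 100
  }
  list(fine_uV = fine_uV, fine_dt = dt,
       pulse_s = length(fine_uV) * dt,
       v_end_uV = fine_uV[length(fine_uV)],
       baseline_uV = baseline_uV,
       tau_rec_s = tau_rec_us * 1e-6, tau_base_s = tau_base_ms * 1e-3)
}

# Render artifact components onto the recording grid. Bins overlapping
# the pulse hold the signed extremum of the fine-grid voltage in that
# sample period (the converter sees the excursion even when a 20-40 us
# pulse is sub-sample at 20 kHz); later samples follow the analytic decay.
render_artifact <- function(comp, sample_rate, n_samples) {
  t_rec <- (seq_len(n_samples) - 1) / sample_rate
  out <- numeric(n_samples)
  after <- t_rec >= comp$pulse_s
  dtail <- t_rec[after] - comp$pulse_s
  out[after] <- comp$v_end_uV * exp(-dtail / comp$tau_rec_s) +
    comp$baseline_uV * exp(-dtail / comp$tau_base_s)
  k_pulse <- which(!after)
  t_fine <- (seq_along(comp$fine_uV) - 1) * comp$fine_dt
  for (k in k_pulse) {
    in_bin <- t_fine >= t_rec[k] & t_fine < t_rec[k] + 1 / sample_rate
    if (any(in_bin)) {
      x <- comp$fine_uV[in_bin]
      out[k] <- x[which.max(abs(x))]
    }
  }
  out
}

#' Simulate a stimulation artifact at the recording grid
#'
#' Artifact recorded on an electrode at a given lateral distance from the
#' stimulation site: the electrode-interface response to the waveform,
#' decayed spatially as `exp(-distance/lambda_art)`, rendered at 20 kHz
#' and clipped at the amplifier saturation limit. Voltage-mode artifacts
#' additionally carry an exponentially decaying baseline offset. Artifact
#' duration grows with pulse duration; short current pulses recover to
#' baseline much faster than the longer voltage pulses.
#'
#' @param mode `"voltage"` or `"current"` (must match the waveform).
#' @param waveform A `stim_waveform`.
#' @param circuit An [electrode_circuit()].
#' @param distance_um Lateral distance from the stimulation electrode.
#' @param saturation_limit_mV Clipping limit (default 3 mV).
#' @param sample_rate Recording rate in Hz.
#' @param duration_s Length of the returned trace.
#' @param lambda_art_um Artifact spatial decay constant (default 100 um).
#' @param tau_rec_us Post-pulse amplifier recovery constant (default 15 us).
#' @param baseline_shift_uV_per_100mV Voltage-mode baseline offset per
#'   100 mV of drive (default 50 uV).
#' @param tau_base_ms Baseline-offset decay constant (default 0.5 ms).
#' @return Numeric artifact trace in uV, onset at the first sample.
#' @export
simulate_artifact <- function(mode, waveform, circuit, distance_um = 0,
                              saturation_limit_mV = 3, sample_rate = 20000,
                              duration_s = 0.005, lambda_art_um = 100,
                              tau_rec_us = 15,
                              baseline_shift_uV_per_100mV = 50,
                              tau_base_ms = 0.5) {
  stopifnot(inherits(waveform, "stim_waveform"), inherits(circuit, "electrode_circuit"))
  if (mode != waveform$mode) stop_mea("mode '%s' does not match waveform mode '%s'", mode, waveform$mode)
  if (distance_um < 0) stop_mea("distance_um must be >= 0")
  comp <- artifact_components(mode, waveform, circuit, tau_rec_us,
                              baseline_shift_uV_per_100mV, tau_base_ms)
  art <- render_artifact(comp, sample_rate, round(duration_s * sample_rate))
  art <- art * exp(-distance_um / lambda_art_um)
  pmin(pmax(art, -saturation_limit_mV * 1000), saturation_limit_mV * 1000)
}

#' Simulate a full stimulation session
#'
#' Runs a randomized stimulation protocol against a synthetic neuron:
#' for every pulse the injected charge is computed per mode (q = I t in
#' current mode; q = C_dl dv in voltage mode), the response is drawn
#' Bernoulli from the neuron's logistic activation model, responding
#' pulses insert the EAP footprint at a truncated-Gaussian latency inside
#' the 1.5 ms window, and the stimulation artifact is added on every
#' electrode with spatial decay. The stimulation electrode defaults to
#' the footprint argmax (the AIS electrode), mirroring the experimental
#' electrode-selection rule. A stimulus-free lead-in segment precedes the
#' first pulse so detection can estimate the noise level from it.
#'
#' @param protocol A [randomize_protocol()] result.
#' @param neuron,geometry,circuit Scene components.
#' @param seed Session seed (noise, responses, latencies).
#' @param noise_rms_uV,sample_rate,saturation_limit_mV Recording model.
#' @param stim_electrode Electrode index; default footprint argmax.
#' @param lead_in_s Stimulus-free lead-in (default 1 s).
#' @param spontaneous_rate_hz Optional Poisson background firing of the
#'   same neuron (default 0).
#' @param delta_v_convention Voltage-excursion convention for voltage-mode
#'   charge (see [voltage_excursion()]).
#' @param lambda_art_um,tau_rec_us,baseline_shift_uV_per_100mV,tau_base_ms
#'   Artifact model, as in [simulate_artifact()].
#' @return Object of class `stim_session`: list(block, ground_truth,
#'   protocol, stim_electrode, footprint, neuron, circuit, lead_in_s,
#'   spontaneous_times_s).
#' @export
simulate_session <- function(protocol, neuron, geometry, circuit, seed = 1,
                             noise_rms_uV = 2.4, sample_rate = 20000,
                             saturation_limit_mV = 3, stim_electrode = NULL,
                             lead_in_s = 1, spontaneous_rate_hz = 0,
                             delta_v_convention = c("half_vpp", "vpp"),
                             lambda_art_um = 100, tau_rec_us = 15,
                             baseline_shift_uV_per_100mV = 50,
                             tau_base_ms = 0.5) {
  stopifnot(inherits(protocol, "stim_protocol"))
  delta_v_convention <- match.arg(delta_v_convention)
  fp <- eap_footprint(neuron, geometry)
  stim_electrode <- stim_electrode %||% which.max(fp)
  if (stim_electrode < 1 || stim_electrode > n_electrodes(geometry)) {
    stop_mea("stim_electrode out of range for this geometry")
  }
  sched <- protocol$schedule
  conds <- protocol$conditions

  charge_of <- function(w) {
    if (w$mode == "current") {
      charge_per_phase_current(w$amplitude, w$phase_duration_us)
    } else {
      charge_voltage_mode(circuit$C_dl * 1e9,
                          voltage_excursion(w$amplitude, w$shape, delta_v_convention))
    }
  }
  cond_charge <- vapply(conds, charge_of, 0)
  cond_artifact <- lapply(conds, function(w) {
    comp <- artifact_components(w$mode, w, circuit, tau_rec_us,
                                baseline_shift_uV_per_100mV, tau_base_ms)
    render_artifact(comp, sample_rate, round(0.005 * sample_rate))
  })
  d_stim <- electrode_distances(geometry,
                                c(geometry$positions$x[stim_electrode],
                                  geometry$positions$y[stim_electrode]))
  art_scale <- exp(-d_stim / lambda_art_um)

  n_pulses <- nrow(sched)
  total_s <- lead_in_s + (n_pulses - 1) / protocol$rate + 0.1
  n_s <- ceiling(total_s * sample_rate)
  n_el <- n_electrodes(geometry)
  tmpl <- eap_template(sample_rate)
  sat_uV <- saturation_limit_mV * 1000

  with_seed(seed, {
    traces <- matrix(stats::rnorm(n_el * n_s, 0, noise_rms_uV), n_el, n_s)

    spont_times <- numeric(0)
    if (spontaneous_rate_hz > 0) {
      n_spont <- stats::rpois(1, total_s * spontaneous_rate_hz)
      spont_times <- sort(stats::runif(n_spont, 0.05, total_s - 0.05))
      for (tt in spont_times) {
        sp <- insert_span(n_s, tmpl$samples, tmpl$trough_index,
                          round(tt * sample_rate) + 1)
        traces[, sp$cols] <- traces[, sp$cols] + outer(fp, sp$values)
      }
    }

    q <- cond_charge[sched$condition_id]
    p <- response_probability(neuron, q)
    responded <- stats::runif(n_pulses) < p
    latency <- rep(NA_real_, n_pulses)
    if (any(responded)) {
      latency[responded] <- rtruncnorm1(sum(responded),
                                        neuron$latency_mean_ms,
                                        neuron$latency_sd_ms,
                                        neuron$latency_min_ms,
                                        neuron$latency_max_ms)
    }

    stim_sample <- round((lead_in_s + sched$time_s) * sample_rate) + 1
    for (i in seq_len(n_pulses)) {
      art <- cond_artifact[[sched$condition_id[i]]]
      sp <- insert_span(n_s, art, 1L, stim_sample[i])
      traces[, sp$cols] <- traces[, sp$cols] + outer(art_scale, sp$values)
      if (responded[i]) {
        at <- stim_sample[i] + round(latency[i] * sample_rate / 1000)
        sp <- insert_span(n_s, tmpl$samples, tmpl$trough_index, at)
        traces[, sp$cols] <- traces[, sp$cols] + outer(fp, sp$values)
      }
    }
    traces <- clip_traces(traces, sat_uV)

    art_peak <- vapply(cond_artifact, function(a) max(abs(a)), 0)
    gt <- data.frame(
      pulse_index = sched$pulse_index,
      condition_id = sched$condition_id,
      mode = sched$mode, shape = sched$shape,
      duration_us = sched$duration_us, amplitude = sched$amplitude,
      charge_pC = q, p_response = p, responded = responded,
      latency_ms = latency,
      stim_electrode = stim_electrode,
      artifact_peak_uV = pmin(art_peak[sched$condition_id], sat_uV),
      stim_time_s = lead_in_s + sched$time_s,
      stringsAsFactors = FALSE
    )
    block <- new_recording_block(geometry, sample_rate, traces, noise_rms_uV,
                                 sat_uV, seed)
    structure(
      list(block = block, ground_truth = gt, protocol = protocol,
           stim_electrode = stim_electrode, footprint = fp, neuron = neuron,
           circuit = circuit, lead_in_s = lead_in_s,
           spontaneous_times_s = spont_times),
      class = "stim_session"
    )
  })
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("<stim_session> %d pulses, stim electrode %d, %d responses (ground truth)\n",
              nrow(x$ground_truth), x$stim_electrode, sum(x$ground_truth$responded)))
  invisible(x)
}

#' Simulate a development series of stimulation sessions
#'
#' One session per recording day ("DIV") for a neuron whose excitability
#' (q50) and position may drift between days, emulating tracking a
#' developing neuron across DIVs. The stimulation electrode is re-selected
#' each session as the footprint argmax, as in the experiments; a
#' between-session displacement beyond two electrode pitches (35 um at
#' default pitch) is allowed but flagged with a warning.
#'
#' @param neurons List of [synthetic_neuron()]s, one per session (>= 2).
#' @param geometry,circuit Shared scene components.
#' @param conditions Protocol condition list (shared across sessions).
#' @param repetitions,rate Protocol parameters (defaults 30 and 1 Hz).
#' @param seed Master seed; each session derives its own sub-seeds.
#' @param ... Further arguments passed to [simulate_session()].
#' @return List of `stim_session` objects.
#' @export
simulate_development_series <- function(neurons, geometry, circuit, conditions,
                                        repetitions = 30, rate = 1, seed = 1, ...) {
  if (length(neurons) < 2) stop_mea("need >= 2 sessions in a development series")
  stopifnot(all(vapply(neurons, inherits, TRUE, "synthetic_neuron")))
  max_shift <- 2 * geometry$pitch_um
  sessions <- vector("list", length(neurons))
  for (i in seq_along(neurons)) {
    if (i > 1) {
      shift <- sqrt(sum((neurons[[i]]$ais_position_um -
                           neurons[[i - 1]]$ais_position_um)^2))
      if (shift > max_shift + 1e-9) {
        warning(sprintf("session %d: neuron moved %.1f um, beyond two electrode pitches (%.1f um)",
                        i, shift, max_shift), call. = FALSE)
      }
    }
    prot <- randomize_protocol(conditions, repetitions, rate,
                               seed = derive_seed(seed, i))
    sessions[[i]] <- simulate_session(prot, neurons[[i]], geometry, circuit,
                                      seed = derive_seed(seed, 1000 + i), ...)
  }
  sessions
}
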