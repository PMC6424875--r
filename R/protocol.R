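#' Condition grids of the stimulation protocols
#'
#' Convenience constructors for the study's condition grids: in voltage
#' mode four waveforms x four per-phase durations (50, 100, 150, 200 us) x
#' six peak-to-peak amplitudes (40-240 mV); in current mode two
#' charge-balanced waveforms x five durations (10, 15, 18, 20, 50 us) x
#' eight amplitudes (42-189 nA).
#'
#' @param shapes,durations_us,amplitudes Optional overrides of the default
#'   grid.
#' @param sample_rate Synthesis rate passed to [build_waveform()].
#' @return A list of `stim_waveform` objects, one per condition.
#' @export
voltage_protocol_conditions <- function(shapes = c("biphasic_cathodic_anodic",
                                                   "biphasic_anodic_cathodic",
                                                   "monophasic_anodic",
                                                   "monophasic_cathodic"),
                                        durations_us = c(50, 100, 150, 200),
                                        amplitudes = c(40, 80, 120, 160, 200, 240),
                                        sample_rate = 1e6) {
  grid <- expand.grid(shape = shapes, duration = durations_us,
                      amplitude = amplitudes, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    build_waveform("voltage", grid$shape[i], grid$duration[i], grid$amplitude[i],
                   sample_rate)
  })
}

#' @rdname voltage_protocol_conditions
#' @export
current_protocol_conditions <- function(shapes = c("biphasic_anodic_cathodic",
                                                   "triphasic_anodic_cathodic_anodic"),
                                        durations_us = c(10, 15, 18, 20, 50),
                                        amplitudes = c(42, 63, 84, 105, 126, 147, 168, 189),
                                        sample_rate = 1e6) {
  grid <- expand.grid(shape = shapes, duration = durations_us,
                      amplitude = amplitudes, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    build_waveform("current", grid$shape[i], grid$duration[i], grid$amplitude[i],
                   sample_rate)
  })
}

condition_label <- function(w) {
  sprintf("%s|%s|%g|%g", w$mode, w$shape, w$phase_duration_us, w$amplitude)
}

#' Randomized stimulation protocol
#'
#' Expands each condition to `repetitions` pulses and applies one seeded
#' global permutation over all pulses, so that repetitions of a condition
#' are scattered across the whole protocol (avoiding plasticity induction
#' by blocked repeats). Pulses are delivered at `rate` Hz.
#'
#' @param conditions Non-empty list of `stim_waveform` objects, one per
#'   distinct condition.
#' @param repetitions Repetitions per condition (default 30).
#' @param rate Stimulation rate in Hz (default 1).
#' @param seed Integer seed; identical seeds give identical orders.
#' @return An object of class `stim_protocol`: list with the `conditions`,
#'   a `schedule` data frame (pulse_index, time_s, condition_id, shape,
#'   duration_us, amplitude, repetition), and the call parameters.
#' @export
randomize_protocol <- function(conditions, repetitions = 30, rate = 1, seed = 1) {
  if (!length(conditions)) stop_mea("conditions must be non-empty")
  if (repetitions < 1) stop_mea("repetitions must be >= 1")
  stopifnot(all(vapply(conditions, inherits, TRUE, "stim_waveform")))
  n_cond <- length(conditions)
  cond_id <- rep(seq_len(n_cond), each = repetitions)
  repetition <- rep(seq_len(repetitions), times = n_cond)
  ord <- with_seed(seed, sample.int(length(cond_id)))
  cond_id <- cond_id[ord]
  repetition <- repetition[ord]
  n <- length(cond_id)
  schedule <- data.frame(
    pulse_index = seq_len(n),
    time_s = (seq_len(n) - 1) / rate,
    condition_id = cond_id,
    mode = vapply(conditions[cond_id], `[[`, "", "mode"),
    shape = vapply(conditions[cond_id], `[[`, "", "shape"),
    duration_us = vapply(conditions[cond_id], `[[`, 0, "phase_duration_us"),
    amplitude = vapply(conditions[cond_id], `[[`, 0, "amplitude"),
    repetition = repetition,
    stringsAsFactors = FALSE
  )
  structure(
    list(conditions = conditions, schedule = schedule,
         repetitions_per_condition = repetitions, rate = rate, seed = seed),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d conditions x %d repetitions = %d pulses @ %g Hz (seed %d)\n",
              length(x$conditions), x$repetitions_per_condition,
              nrow(x$schedule), x$rate, x$seed))
  invisible(x)
}

#' Write / read a protocol pulse table
#'
#' The emitted pulse table is a plain delimited-text mirror of the
#' schedule, one row per pulse.
#'
#' @param protocol A `stim_protocol`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_protocol_table <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  utils::write.csv(protocol$schedule, path, row.names = FALSE)
  invisible(path)
}
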