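#' Detection configuration
#'
#' Parameters of the threshold detectors: spontaneous spikes are called at
#' 4.5 x the noise SD, evoked responses at 4 x the noise SD inside a
#' 1.5 ms post-stimulus window. A blanking interval after stimulus onset
#' (pulse duration plus a mode-dependent recovery margin) is excluded from
#' the evoked search because the artifact dominates it.
#'
#' @param spontaneous_threshold_k Threshold multiple for spontaneous
#'   detection (default 4.5).
#' @param evoked_threshold_k Threshold multiple for evoked detection
#'   (default 4).
#' @param evoked_window_ms Post-stimulus search window (default 1.5 ms).
#' @param blanking_margin_voltage_us,blanking_margin_current_us Recovery
#'   margin added to the pulse duration for the blanking interval
#'   (defaults 300 us in voltage mode, 100 us in current mode; current
#'   artifacts recover visibly faster).
#' @param noise_estimator `"sd"` or `"mad"` (MAD is scaled to be
#'   Gaussian-consistent and robust to spike contamination).
#' @param min_below Consecutive sub-threshold samples required for a
#'   crossing (default 2; guards against single-sample excursions of
#'   unfiltered white noise).
#' @param refractory_ms Merge window for crossings belonging to one spike
#'   (default 1 ms).
#' @param indeterminate_saturation_frac If saturated samples cover more
#'   than this fraction of the evoked window the pulse is classed
#'   indeterminate (default 0.5), the automated analogue of the
#'   artifact-covered "missing EAP" case that required manual inspection.
#' @param count_indeterminate_as_failure If `FALSE` (default)
#'   indeterminate pulses are excluded from the denominator of efficiency
#'   tables; if `TRUE` they count as failures. Both conventions for
#'   entering the 30-pulse denominators are supported.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(spontaneous_threshold_k = 4.5,
                             evoked_threshold_k = 4,
                             evoked_window_ms = 1.5,
                             blanking_margin_voltage_us = 300,
                             blanking_margin_current_us = 100,
                             noise_estimator = c("sd", "mad"),
                             min_below = 2,
                             refractory_ms = 1,
                             indeterminate_saturation_frac = 0.5,
                             count_indeterminate_as_failure = FALSE) {
  noise_estimator <- match.arg(noise_estimator)
  if (spontaneous_threshold_k <= 0 || evoked_threshold_k <= 0) {
    stop_mea("thresholds must be > 0")
  }
  structure(
    list(spontaneous_threshold_k = spontaneous_threshold_k,
         evoked_threshold_k = evoked_threshold_k,
         evoked_window_ms = evoked_window_ms,
         blanking_margin_voltage_us = blanking_margin_voltage_us,
         blanking_margin_current_us = blanking_margin_current_us,
         noise_estimator = noise_estimator,
         min_below = min_below, refractory_ms = refractory_ms,
         indeterminate_saturation_frac = indeterminate_saturation_frac,
         count_indeterminate_as_failure = count_indeterminate_as_failure),
    class = "detection_config"
  )
}

# Blanking interval (ms) after stimulus onset for a condition.
blanking_ms <- function(mode, n_phases, duration_us, config) {
  margin <- if (mode == "voltage") config$blanking_margin_voltage_us
            else config$blanking_margin_current_us
  (n_phases * duration_us + margin) / 1000
}

#' Noise level of a trace
#'
#' Scale estimate of the recording noise, either the plain standard
#' deviation or the Gaussian-consistent MAD (robust against sparse spikes
#' or outliers). Requires at least 0.5 s of signal.
#'
#' @param trace Numeric trace in uV.
#' @param estimator `"sd"` or `"mad"`.
#' @param sample_rate Hz, used only for the minimum-length check.
#' @return Noise SD estimate in uV.
#' @export
noise_sd <- function(trace, estimator = c("sd", "mad"), sample_rate = 20000) {
  estimator <- match.arg(estimator)
  if (length(trace) < 0.5 * sample_rate) {
    stop_mea("trace too short for a noise estimate (need >= 0.5 s, got %.3g s)",
             length(trace) / sample_rate)
  }
  if (estimator == "sd") stats::sd(trace) else stats::mad(trace)
}

# Indices of negative-going crossings: runs of >= min_below consecutive
# samples below `threshold` (a negative value); one trough index per run.
threshold_crossings <- function(trace, threshold, min_below) {
  below <- !is.na(trace) & trace < threshold
  if (!any(below)) return(integer(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_below
  vapply(which(keep), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.min(trace[seg])]
  }, 0L)
}

merge_refractory <- function(troughs, trace, refractory_samples) {
  if (length(troughs) <= 1) return(troughs)
  out <- troughs[1]
  for (k in troughs[-1]) {
    last <- out[length(out)]
    if (k - last < refractory_samples) {
      if (trace[k] < trace[last]) out[length(out)] <- k
    } else {
      out <- c(out, k)
    }
  }
  out
}

#' Detect spontaneous spikes on a trace
#'
#' Negative-going threshold crossings at `-k * SD` of the noise, with
#' crossings closer than the refractory window merged into one event
#' (keeping the deeper trough). Times are reported at the trough.
#'
#' @param trace Numeric trace (uV).
#' @param config A [detection_config()].
#' @param sample_rate Hz.
#' @param noise_sd_uV Optional precomputed noise SD; estimated from the
#'   trace itself otherwise.
#' @return Spike trough times in seconds.
#' @export
detect_spikes <- function(trace, config = detection_config(),
                          sample_rate = 20000, noise_sd_uV = NULL) {
  stopifnot(inherits(config, "detection_config"))
  sd_uV <- noise_sd_uV %||% noise_sd(trace, config$noise_estimator, sample_rate)
  thr <- -config$spontaneous_threshold_k * sd_uV
  troughs <- threshold_crossings(trace, thr, config$min_below)
  troughs <- merge_refractory(troughs, trace,
                              round(config$refractory_ms * sample_rate / 1000))
  (troughs - 1) / sample_rate
}

#' Detect an evoked response after one stimulus
#'
#' Searches the readout electrode for a crossing of `-4 x SD` inside
#' `(stim + blanking, stim + 1.5 ms]`. Samples inside the blanking
#' interval are ignored; saturated samples are excluded from the search
#' and, when they cover more than half of the window, the pulse is
#' classed indeterminate (the artifact obscured the window). The readout
#' electrode must differ from the stimulation electrode.
#'
#' @param block A `recording_block`.
#' @param stim_time_s Stimulus onset time in seconds.
#' @param stim_electrode,readout_electrode Electrode indices.
#' @param config A [detection_config()].
#' @param noise_sd_uV Noise SD of the readout electrode (uV).
#' @param blanking_ms Blanking interval after onset in ms (must be smaller
#'   than the evoked window).
#' @return List with `responded`, `latency_ms` (NA when not responded) and
#'   `indeterminate`.
#' @export
detect_evoked <- function(block, stim_time_s, stim_electrode, readout_electrode,
                          config = detection_config(), noise_sd_uV,
                          blanking_ms = 0.2) {
  stopifnot(inherits(block, "recording_block"), inherits(config, "detection_config"))
  if (readout_electrode == stim_electrode) {
    stop_mea("readout electrode must differ from the stimulation electrode")
  }
  if (blanking_ms >= config$evoked_window_ms) {
    stop_mea("blanking (%g ms) must be smaller than the evoked window (%g ms)",
             blanking_ms, config$evoked_window_ms)
  }
  sr <- block$sample_rate
  stim_sample <- round(stim_time_s * sr) + 1
  from <- stim_sample + floor(blanking_ms * sr / 1000) + 1
  to <- stim_sample + round(config$evoked_window_ms * sr / 1000)
  if (to > ncol(block$traces)) {
    stop_mea("evoked window extends past the end of the recording")
  }
  win <- block$traces[readout_electrode, from:to]
  saturated <- abs(win) >= block$saturation_limit_uV - 1e-9
  if (mean(saturated) > config$indeterminate_saturation_frac) {
    return(list(responded = NA, latency_ms = NA_real_, indeterminate = TRUE))
  }
  win[saturated] <- NA_real_
  thr <- -config$evoked_threshold_k * noise_sd_uV
  troughs <- threshold_crossings(win, thr, config$min_below)
  if (!length(troughs)) {
    return(list(responded = FALSE, latency_ms = NA_real_, indeterminate = FALSE))
  }
  trough_sample <- from + troughs[1] - 1
  list(responded = TRUE,
       latency_ms = (trough_sample - stim_sample) * 1000 / sr,
       indeterminate = FALSE)
}

#' Efficiency table of a stimulation session
#'
#' Runs the evoked detector on every pulse of a session (using only the
#' protocol timing, never the ground truth) and aggregates success counts
#' per condition. The noise SD is estimated from the stimulus-free
#' lead-in segment of the readout electrode. Indeterminate pulses are
#' tallied separately and, by default, excluded from `n_total`.
#'
#' @param session A `stim_session`.
#' @param config A [detection_config()].
#' @param readout_electrode Readout electrode index; defaults to the
#'   nearest neighbor of the stimulation electrode (17.5 um away at
#'   default pitch).
#' @return Object of class `efficiency_table`: data frame with one row
#'   per condition (condition_id, mode, shape, duration_us, amplitude,
#'   charge_pC, n_success, n_total, n_indeterminate).
#' @export
efficiency_table <- function(session, config = detection_config(),
                             readout_electrode = NULL) {
  stopifnot(inherits(session, "stim_session"))
  block <- session$block
  geom <- block$geometry
  stim <- session$stim_electrode
  if (is.null(readout_electrode)) {
    d <- electrode_distances(geom, c(geom$positions$x[stim], geom$positions$y[stim]))
    d[stim] <- Inf
    readout_electrode <- which.min(d)
  }
  sr <- block$sample_rate
  lead_n <- floor((session$lead_in_s - 0.01) * sr)
  sd_uV <- noise_sd(block$traces[readout_electrode, seq_len(lead_n)],
                    config$noise_estimator, sr)

  sched <- session$protocol$schedule
  res <- lapply(seq_len(nrow(sched)), function(i) {
    w <- session$protocol$conditions[[sched$condition_id[i]]]
    bl <- blanking_ms(w$mode, w$n_phases, w$phase_duration_us, config)
    detect_evoked(block, session$lead_in_s + sched$time_s[i], stim,
                  readout_electrode, config, sd_uV, bl)
  })
  responded <- vapply(res, function(r) isTRUE(r$responded), TRUE)
  indet <- vapply(res, `[[`, TRUE, "indeterminate")

  ids <- sort(unique(sched$condition_id))
  rows <- lapply(ids, function(id) {
    sel <- sched$condition_id == id
    w <- session$protocol$conditions[[id]]
    n_ind <- sum(indet[sel])
    n_tot <- sum(sel) - if (config$count_indeterminate_as_failure) 0 else n_ind
    data.frame(condition_id = id, mode = w$mode, shape = w$shape,
               duration_us = w$phase_duration_us, amplitude = w$amplitude,
               charge_pC = session$ground_truth$charge_pC[which(sel)[1]],
               n_success = sum(responded[sel] & !indet[sel]),
               n_total = n_tot, n_indeterminate = n_ind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "readout_electrode") <- readout_electrode
  attr(out, "noise_sd_uV") <- sd_uV
  attr(out, "config") <- config
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Activation curves and 90%-efficiency thresholds
#'
#' For every (mode, shape, phase duration) the per-amplitude success
#' fractions form an activation curve; the activation threshold is the
#' smallest tested amplitude whose success count reaches
#' [min_successes_for_efficiency()] (27 of 30 at the default 90%
#' criterion). When no tested amplitude reaches it the threshold is
#' reported as not reached (`NA`), the session's failure case.
#'
#' @param table An [efficiency_table()] (or compatible data frame).
#' @param efficiency Efficiency criterion (default 0.9).
#' @return Object of class `activation_curve`: list with `curves` (per-
#'   amplitude fractions) and `thresholds` (one row per shape/duration
#'   with `threshold` = amplitude or NA, `threshold_charge_pC`, `reached`).
#' @export
activation_threshold <- function(table, efficiency = 0.9) {
  if (!nrow(table)) stop_mea("empty efficiency table")
  table <- table[order(table$mode, table$shape, table$duration_us, table$amplitude), ]
  key <- interaction(table$mode, table$shape, table$duration_us, drop = TRUE)
  curves <- data.frame(table,
                       fraction = ifelse(table$n_total > 0,
                                         table$n_success / table$n_total, NA_real_))
  thr <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, ]
    need <- vapply(sub$n_total, function(n) {
      if (n < 1) return(NA_integer_)
      as.integer(min_successes_for_efficiency(n, efficiency))
    }, 0L)
    hit <- which(!is.na(need) & sub$n_success >= need)
    data.frame(mode = sub$mode[1], shape = sub$shape[1],
               duration_us = sub$duration_us[1],
               threshold = if (length(hit)) sub$amplitude[hit[1]] else NA_real_,
               threshold_charge_pC = if (length(hit)) sub$charge_pC[hit[1]] else NA_real_,
               reached = length(hit) > 0,
               stringsAsFactors = FALSE)
  })
  structure(list(curves = curves, thresholds = do.call(rbind, thr),
                 efficiency = efficiency),
            class = "activation_curve")
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("<activation_curve> %d%% criterion\n", round(100 * x$efficiency)))
  print(x$thresholds, row.names = FALSE)
  invisible(x)
}

#' Normalize a threshold series to its maximum
#'
#' Cross-session comparison of activation thresholds: each session's
#' threshold divided by the series maximum, giving relative amplitudes in
#' (0, 1]. Not-reached thresholds (NA) propagate as missing.
#'
#' @param thresholds Numeric vector of per-session thresholds (amplitude
#'   or charge), NA where the criterion was not reached.
#' @return Numeric vector of relative amplitudes.
#' @export
normalize_threshold_series <- function(thresholds) {
  if (all(is.na(thresholds))) stop_mea("all thresholds missing: nothing to normalize")
  thresholds / max(thresholds, na.rm = TRUE)
}
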