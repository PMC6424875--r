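#' Synthetic single neuron for recording simulation
#'
#' Parameterizes the features of a cultured neuron that the recordings
#' depend on: where its axon initial segment (AIS) sits on the array (the
#' site of the largest extracellular action potential and the most
#' stimulation-sensitive compartment), the EAP amplitude and its spatial
#' decay across electrodes, and a stochastic activation model in injected
#' charge. The response to a pulse of charge q is Bernoulli with
#' probability `p_max / (1 + exp(-(q - q50)/slope))`: a logistic link in
#' charge, the minimal model producing the monotone activation curves seen
#' experimentally (the activation model is synthetic; the study reports
#' only empirical curves).
#'
#' Evoked latencies are drawn from a Gaussian truncated to
#' `[latency_min_ms, latency_max_ms]`; the upper bound is the 1.5 ms
#' evoked-response window. The lower bound keeps evoked spikes clear of
#' the stimulation artifact blanking interval.
#'
#' @param soma_position_um,ais_position_um Positions c(x, y) in um.
#' @param peak_amplitude_uV EAP trough magnitude at the AIS electrode in
#'   uV (default 150).
#' @param decay_um Exponential spatial decay constant of the footprint in
#'   um (default 25; footprints span a few electrodes at 17.5 um pitch).
#' @param q50_pC Charge at 50% of the maximal response probability.
#' @param slope_pC Logistic slope in pC.
#' @param p_max Maximal response probability (<= 1).
#' @param latency_mean_ms,latency_sd_ms,latency_min_ms,latency_max_ms
#'   Evoked-latency distribution (ms).
#' @return Object of class `synthetic_neuron`.
#' @export
synthetic_neuron <- function(soma_position_um, ais_position_um = soma_position_um,
                             peak_amplitude_uV = 150, decay_um = 25,
                             q50_pC = 1.5, slope_pC = 0.15, p_max = 1,
                             latency_mean_ms = 0.8, latency_sd_ms = 0.15,
                             latency_min_ms = 0.4, latency_max_ms = 1.5) {
  if (p_max > 1 || p_max < 0) stop_mea("p_max must be in [0, 1]")
  if (q50_pC <= 0) stop_mea("q50_pC must be > 0")
  if (slope_pC <= 0) stop_mea("slope_pC must be > 0")
  if (latency_min_ms <= 0 || latency_max_ms > 1.5 || latency_min_ms >= latency_max_ms) {
    stop_mea("latencies must satisfy 0 < latency_min_ms < latency_max_ms <= 1.5")
  }
  structure(
    list(soma_position_um = soma_position_um, ais_position_um = ais_position_um,
         peak_amplitude_uV = peak_amplitude_uV, decay_um = decay_um,
         q50_pC = q50_pC, slope_pC = slope_pC, p_max = p_max,
         latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
         latency_min_ms = latency_min_ms, latency_max_ms = latency_max_ms),
    class = "synthetic_neuron"
  )
}

#' Response probability of a neuron at a given charge
#'
#' @param neuron A [synthetic_neuron()].
#' @param q_pC Injected charge in pC.
#' @return Probability between 0 and `p_max`.
#' @export
response_probability <- function(neuron, q_pC) {
  neuron$p_max / (1 + exp(-(q_pC - neuron$q50_pC) / neuron$slope_pC))
}

#' Extracellular action-potential template
#'
#' Normalized biphasic spike shape (sharp negative trough followed by a
#' smaller positive overshoot), about 1.2 ms long, trough at -1. Returned
#' together with the index of the trough sample so that insertions can be
#' aligned on the trough.
#'
#' @param sample_rate Sampling rate in Hz (default 20 kHz).
#' @return List with `samples` (numeric) and `trough_index`.
#' @export
eap_template <- function(sample_rate = 20000) {
  t_ms <- seq(-0.4, 0.8, by = 1000 / sample_rate)  # ms relative to trough
  trough <- -exp(-(t_ms / 0.1)^2 / 2)
  overshoot <- 0.35 * exp(-((t_ms - 0.35) / 0.25)^2 / 2)
  samples <- trough + overshoot
  samples <- samples / abs(min(samples))
  list(samples = samples, trough_index = which.min(samples))
}

#' Spatial EAP footprint over an electrode array
#'
#' Per-electrode EAP trough amplitude: maximal at the AIS electrode and
#' decaying exponentially with distance, `amplitude(e) = peak *
#' exp(-d(e, ais)/decay)`. Template polarity (negative trough) is carried
#' by the template; the footprint holds positive magnitudes.
#'
#' @param neuron A [synthetic_neuron()].
#' @param geometry An [array_geometry()].
#' @return Numeric vector of trough magnitudes (uV), one per electrode.
#' @export
eap_footprint <- function(neuron, geometry) {
  stopifnot(inherits(neuron, "synthetic_neuron"), inherits(geometry, "array_geometry"))
  if (!point_in_array(geometry, neuron$ais_position_um)) {
    stop_mea("neuron AIS at (%g, %g) um lies outside the array bounds",
             neuron$ais_position_um[1], neuron$ais_position_um[2])
  }
  d <- electrode_distances(geometry, neuron$ais_position_um)
  neuron$peak_amplitude_uV * exp(-d / neuron$decay_um)
}
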