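test_that("noise estimation is accurate and robust to outliers", {
  expect_equal(noise_sd(rep(5, 20000)), 0)
  set.seed(31)
  g <- rnorm(60 * 20000, 0, 2.4)
  expect_lt(abs(noise_sd(g) - 2.4), 0.05)
  # 2% gross outliers barely move the MAD estimate
  contaminated <- g
  idx <- sample(length(g), 0.02 * length(g))
  contaminated[idx] <- contaminated[idx] + sample(c(-1, 1), length(idx), TRUE) * 100
  expect_lt(abs(noise_sd(contaminated, "mad") - 2.4) / 2.4, 0.05)
  expect_error(noise_sd(rnorm(100)), "too short")
})

test_that("spike detection finds 10xSD spikes with high recall and precision", {
  geom <- array_geometry(1, 1)
  neuron <- synthetic_neuron(c(0, 0), peak_amplitude_uV = 24)  # 10 x 2.4 uV
  sim <- simulate_spontaneous(neuron, geom, 60, firing_rate_hz = 2, seed = 8)
  det <- detect_spikes(sim$block$traces[1, ])
  truth <- sim$spike_times_s
  tp <- sum(vapply(truth, function(t) any(abs(det - t) < 5e-4), TRUE))
  expect_gte(tp / length(truth), 0.99)
  expect_gte(tp / length(det), 0.99)
})

test_that("pure noise yields almost no detections and zeros yield none", {
  set.seed(77)
  noise <- rnorm(60 * 20000, 0, 2.4)
  det <- detect_spikes(noise)
  expect_lt(length(det) / 60, 1)  # Gaussian-tail upper bound: < 1 event/s
  expect_length(detect_spikes(rep(0, 20000)), 0)
})

test_that("refractory merging keeps one trough per spike", {
  # two sub-threshold dips 0.4 ms apart merge; 2 ms apart stay separate
  sr <- 20000
  tr <- rep(0, sr)
  tr[1000:1002] <- -20; tr[1008:1010] <- -25
  cfg <- detection_config()
  t1 <- detect_spikes(tr, cfg, sr, noise_sd_uV = 2.4)
  expect_length(t1, 1)
  expect_equal(t1, 1007 / sr)  # the deeper trough wins
  tr[1048:1050] <- -22
  t2 <- detect_spikes(tr, cfg, sr, noise_sd_uV = 2.4)
  expect_length(t2, 2)
})

test_that("evoked detection recovers latency and honours blanking and saturation", {
  geom <- array_geometry(2, 2)
  sr <- 20000
  n_s <- 2 * sr
  traces <- matrix(0, 4, n_s)
  stim_t <- 1.0
  circ <- ptblack_circuit()
  w <- build_waveform("current", "biphasic_anodic_cathodic", 20, 100)
  art <- simulate_artifact("current", w, circ, distance_um = 17.5)
  traces[2, sr + seq_along(art)] <- art
  tmpl <- eap_template(sr)
  at <- sr + round(0.8e-3 * sr)  # trough at +0.8 ms
  idx <- seq(at - tmpl$trough_index + 1, length.out = length(tmpl$samples))
  traces[2, idx] <- traces[2, idx] + tmpl$samples * 6 * 2.4  # 6 x SD EAP
  block <- meastim:::new_recording_block(geom, sr, traces, 2.4, 3000, 1)

  cfg <- detection_config()
  r <- detect_evoked(block, stim_t, 1, 2, cfg, noise_sd_uV = 2.4, blanking_ms = 0.14)
  expect_true(r$responded)
  expect_false(r$indeterminate)
  expect_equal(r$latency_ms, 0.8, tolerance = 0.11)  # within ~2 samples

  # no EAP inserted: not responded
  blank <- meastim:::new_recording_block(geom, sr, matrix(0, 4, n_s), 2.4, 3000, 1)
  r2 <- detect_evoked(blank, stim_t, 1, 2, cfg, noise_sd_uV = 2.4, blanking_ms = 0.14)
  expect_false(r2$responded)

  # artifact saturating the whole window: indeterminate
  sat <- matrix(0, 4, n_s)
  sat[2, (sr + 1):(sr + 40)] <- -3000
  bsat <- meastim:::new_recording_block(geom, sr, sat, 2.4, 3000, 1)
  r3 <- detect_evoked(bsat, stim_t, 1, 2, cfg, noise_sd_uV = 2.4, blanking_ms = 0.14)
  expect_true(r3$indeterminate)

  # contract checks
  expect_error(detect_evoked(block, stim_t, 2, 2, cfg, 2.4, 0.14), "differ")
  expect_error(detect_evoked(block, stim_t, 1, 2, cfg, 2.4, blanking_ms = 2), "smaller")
  expect_error(detect_evoked(block, 2.0 - 1e-4, 1, 2, cfg, 2.4, 0.14), "past the end")
})

test_that("efficiency tables equal ground truth exactly on current-mode sessions", {
  # the central detector/ground-truth agreement property, across seeds
  scene <- tiny_scene(q50_pC = 1.8, slope_pC = 0.3)
  for (s in 1:8) {
    ses <- tiny_session(s, amplitudes = c(42, 105, 189), scene = scene)
    eff <- efficiency_table(ses)
    expect_identical(eff$n_success, gt_counts(ses))
    expect_true(all(eff$n_total == 30))
    expect_true(all(eff$n_indeterminate == 0))
  }
})

test_that("activation thresholds implement the 90%-of-30 criterion", {
  tab <- data.frame(
    condition_id = 1:6, mode = "voltage", shape = "biphasic_anodic_cathodic",
    duration_us = 100, amplitude = c(40, 80, 120, 160, 200, 240),
    charge_pC = NA_real_, n_success = c(10, 20, 26, 27, 30, 30),
    n_total = 30, n_indeterminate = 0
  )
  act <- activation_threshold(tab)
  expect_equal(act$thresholds$threshold, 160)
  expect_true(act$thresholds$reached)

  tab$n_success <- rep(30, 6)
  expect_equal(activation_threshold(tab)$thresholds$threshold, 40)

  tab$n_success <- rep(26, 6)  # never reaches 27/30
  act3 <- activation_threshold(tab)
  expect_false(act3$thresholds$reached)
  expect_true(is.na(act3$thresholds$threshold))

  expect_error(activation_threshold(tab[0, ]), "empty")
})

test_that("success fractions rise monotonically with amplitude for sharp generators", {
  scene <- tiny_scene(q50_pC = 2.1, slope_pC = 0.02)  # slope -> 0 limit
  ses <- tiny_session(5, amplitudes = c(42, 84, 105, 126, 189), scene = scene)
  eff <- efficiency_table(ses)
  ord <- order(eff$amplitude)
  expect_true(all(diff(eff$n_success[ord]) >= 0))
  # threshold brackets the q50-implied amplitude: q50 = 2.1 pC = 105 nA x 20 us
  act <- activation_threshold(eff)
  expect_equal(act$thresholds$threshold_charge_pC, 2.52)  # first grid point above q50
})

test_that("indeterminate pulses never inflate success counts", {
  # voltage-mode sessions saturate readout neighbours; compare against truth
  geom <- array_geometry(2, 2)
  neuron <- synthetic_neuron(c(0, 0), q50_pC = 50, slope_pC = 10, p_max = 1)
  circ <- ptblack_circuit()
  conds <- voltage_protocol_conditions(shapes = "biphasic_anodic_cathodic",
                                       durations_us = 100, amplitudes = c(80, 240))
  prot <- randomize_protocol(conds, 15, seed = 40)
  ses <- simulate_session(prot, neuron, geom, circ, seed = 41)
  eff <- efficiency_table(ses)
  expect_true(all(eff$n_success <= gt_counts(ses)))
  expect_true(all(eff$n_total + eff$n_indeterminate == 15))
})

test_that("threshold series normalize to their maximum with missing propagation", {
  expect_equal(normalize_threshold_series(c(126, 105, 84, 84)),
               c(1, 105 / 126, 84 / 126, 84 / 126))
  expect_equal(normalize_threshold_series(c(100, 100)), c(1, 1))
  expect_equal(normalize_threshold_series(c(126, NA, 84)),
               c(1, NA, 84 / 126))
  expect_error(normalize_threshold_series(c(NA_real_, NA_real_)), "all thresholds")
})

test_that("development series with decreasing excitability yields non-increasing thresholds", {
  geom <- array_geometry(2, 2)
  circ <- ptblack_circuit()
  conds <- current_protocol_conditions(shapes = "biphasic_anodic_cathodic",
                                       durations_us = 20,
                                       amplitudes = c(42, 63, 84, 105, 126, 147, 168, 189))
  q50s <- c(2.6, 2.2, 1.8, 1.8)  # excitability rises, then stabilizes
  neurons <- lapply(q50s, function(q)
    synthetic_neuron(c(0, 0), q50_pC = q, slope_pC = 0.02))
  sessions <- simulate_development_series(neurons, geom, circ, conds,
                                          repetitions = 30, seed = 6)
  thresholds <- vapply(sessions, function(s) {
    activation_threshold(efficiency_table(s))$thresholds$threshold
  }, 0)
  expect_true(all(diff(thresholds) <= 0))
  rel <- normalize_threshold_series(thresholds)
  expect_equal(rel[1], 1)
  expect_true(all(rel > 0 & rel <= 1))
})
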