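test_that("EAP footprint peaks at the AIS and decays exponentially", {
  geom <- array_geometry(4, 4)
  n <- synthetic_neuron(c(17.5, 17.5), peak_amplitude_uV = 200, decay_um = 25)
  fp <- eap_footprint(n, geom)
  ais_el <- which(geom$positions$x == 17.5 & geom$positions$y == 17.5)
  expect_equal(which.max(fp), ais_el)
  expect_equal(fp[ais_el], 200)
  # electrode one decay constant away
  n2 <- synthetic_neuron(c(0, 0), peak_amplitude_uV = 200, decay_um = 17.5)
  fp2 <- eap_footprint(n2, geom)
  el_1pitch <- which(geom$positions$x == 17.5 & geom$positions$y == 0)
  expect_equal(fp2[el_1pitch], 200 / exp(1))
  # monotone decay with distance, brute force over all electrodes
  d <- sqrt(geom$positions$x^2 + geom$positions$y^2)
  expect_true(all(diff(fp2[order(d)]) <= 1e-12))
  expect_error(eap_footprint(synthetic_neuron(c(500, 500)), geom), "outside")
})

test_that("spontaneous simulation matches its Poisson and noise model", {
  geom <- array_geometry(2, 2)
  neuron <- synthetic_neuron(c(0, 0), peak_amplitude_uV = 150)
  sim <- simulate_spontaneous(neuron, geom, 60, firing_rate_hz = 2, seed = 4)
  expect_equal(ncol(sim$block$traces), 60 * 20000)
  expect_lt(abs(length(sim$spike_times_s) - 120), 3 * sqrt(120))

  # zero noise: traces are exactly the template sums
  clean <- simulate_spontaneous(neuron, geom, 5, 2, noise_rms_uV = 0, seed = 9)
  tmpl <- eap_template(20000)
  fp <- eap_footprint(neuron, geom)
  expect_equal(sum(clean$block$traces[1, ] != 0),
               length(clean$spike_times_s) * sum(tmpl$samples != 0))
  expect_equal(min(clean$block$traces[1, ]), -fp[1])

  # seed reproducibility, bit-identical
  again <- simulate_spontaneous(neuron, geom, 5, 2, noise_rms_uV = 0, seed = 9)
  expect_identical(clean$block$traces, again$block$traces)
  expect_identical(clean$spike_times_s, again$spike_times_s)
})

test_that("noise calibration: a signal-free trace has the configured rms", {
  geom <- array_geometry(1, 1)
  mute <- synthetic_neuron(c(0, 0), peak_amplitude_uV = 0)
  sim <- simulate_spontaneous(mute, geom, 60, 2, noise_rms_uV = 2.4, seed = 12)
  expect_lt(abs(stats::sd(sim$block$traces[1, ]) - 2.4) / 2.4, 0.02)
})

test_that("artifact model: scaling, clipping and mode-dependent recovery", {
  circ <- ptblack_circuit()
  zero <- build_waveform("current", "biphasic_anodic_cathodic", 20, 0)
  expect_true(all(simulate_artifact("current", zero, circ) == 0))

  # on-electrode artifact clips at the saturation limit for large drives
  big <- build_waveform("current", "biphasic_anodic_cathodic", 50, 189)
  art_big <- simulate_artifact("current", big, circ, saturation_limit_mV = 3)
  expect_equal(max(abs(art_big)), 3000)

  # spatial decay over distance
  w <- build_waveform("current", "biphasic_anodic_cathodic", 20, 100)
  a0 <- simulate_artifact("current", w, circ, distance_um = 0)
  a1 <- simulate_artifact("current", w, circ, distance_um = 100)
  expect_equal(max(abs(a1)), max(abs(a0)) * exp(-1), tolerance = 1e-6)

  # short current pulse recovers below 4 x noise SD before the longer
  # voltage pulse does
  wv <- build_waveform("voltage", "biphasic_anodic_cathodic", 100, 100)
  ac <- simulate_artifact("current", w, circ, distance_um = 17.5)
  av <- simulate_artifact("voltage", wv, circ, distance_um = 17.5)
  thr <- 4 * 2.4
  last_above <- function(a) max(c(0, which(abs(a) > thr)))
  expect_lt(last_above(ac), last_above(av))
})

test_that("sessions honour the logistic activation model at its extremes", {
  scene <- tiny_scene(q50_pC = 1.5, slope_pC = 0.05)
  # q >> q50 saturates at p_max = 1; q << q50 yields ~0 responses
  ses <- tiny_session(21, amplitudes = c(42, 189), scene = scene)
  counts <- gt_counts(ses)
  expect_equal(counts[1], 0L)   # 0.84 pC, 13 slopes below q50
  expect_equal(counts[2], 30L)  # 3.78 pC, far above
  expect_true(all(abs(ses$block$traces) <= ses$block$saturation_limit_uV))
  # determinism
  ses2 <- tiny_session(21, amplitudes = c(42, 189), scene = scene)
  expect_identical(ses$block$traces, ses2$block$traces)
  expect_identical(ses$ground_truth, ses2$ground_truth)
  # latencies of responders lie inside the evoked window
  lat <- ses$ground_truth$latency_ms[ses$ground_truth$responded]
  expect_true(all(lat > 0 & lat <= 1.5))
})

test_that("response fraction at q50 matches Binomial(30, p_max/2) across seeds", {
  # 105 nA x 20 us = 2.1 pC chosen as q50 so every pulse is a fair coin
  scene <- tiny_scene(q50_pC = 2.1, slope_pC = 0.15)
  counts <- vapply(1:60, function(s) {
    gt_counts(tiny_session(s, amplitudes = 105, repetitions = 30, scene = scene))
  }, 0L)
  expect_lt(abs(mean(counts) / 30 - 0.5), 0.05)
  # chi-square goodness of fit against Binomial(30, 0.5); tails pooled so
  # every expected bin count exceeds 5
  brk <- c(-Inf, 11, 13, 15, 17, Inf)
  obs <- table(cut(counts, brk))
  p <- diff(pbinom(brk, 30, 0.5))
  gof <- stats::chisq.test(as.vector(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("development series re-selects the stimulation electrode as the neuron moves", {
  geom <- array_geometry(3, 3)
  circ <- ptblack_circuit()
  conds <- current_protocol_conditions(shapes = "biphasic_anodic_cathodic",
                                       durations_us = 20, amplitudes = c(42, 189))
  stationary <- lapply(c(2.0, 1.5), function(q)
    synthetic_neuron(c(17.5, 17.5), q50_pC = q))
  s1 <- simulate_development_series(stationary, geom, circ, conds,
                                    repetitions = 5, seed = 2)
  expect_equal(s1[[1]]$stim_electrode, s1[[2]]$stim_electrode)

  # a 35 um shift (two pitches) moves the stimulation electrode two columns
  moving <- list(synthetic_neuron(c(0, 17.5), q50_pC = 2),
                 synthetic_neuron(c(35, 17.5), q50_pC = 2))
  s2 <- simulate_development_series(moving, geom, circ, conds,
                                    repetitions = 5, seed = 2)
  p1 <- geom$positions[s2[[1]]$stim_electrode, ]
  p2 <- geom$positions[s2[[2]]$stim_electrode, ]
  expect_equal(p2$col - p1$col, 2)
  expect_equal(p2$row, p1$row)

  # beyond two pitches: allowed but flagged
  jumping <- list(synthetic_neuron(c(0, 0), q50_pC = 2),
                  synthetic_neuron(c(35, 17.5), q50_pC = 2))
  expect_warning(
    simulate_development_series(jumping, geom, circ, conds,
                                repetitions = 2, seed = 3),
    "beyond two electrode pitches")
})
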