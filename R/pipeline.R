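#' Default end-to-end run configuration
#'
#' A fully serializable configuration from which a run is reproducible
#' (together with nothing else): geometry, neuron, electrode circuit,
#' protocol, detection settings and optional impedance-fit and field-
#' simulation stages. Defaults follow the study conditions: 20 kHz
#' sampling, 2.4 uV rms noise, 17.5 um pitch, 30 repetitions at 1 Hz,
#' 4.5x/4x SD thresholds, 1.5 ms evoked window.
#'
#' @param seed Master seed.
#' @param output_dir Output directory for [run_end_to_end()].
#' @return Nested configuration list, class `run_config`.
#' @export
default_run_config <- function(seed = 1, output_dir = tempfile("meastim_run_")) {
  structure(list(
    schema = 1,
    seed = seed,
    output_dir = output_dir,
    geometry = list(n_rows = 4, n_cols = 4, pitch_um = 17.5,
                    electrode_size_um = c(5, 9)),
    neuron = list(soma_position_um = c(26.25, 26.25),
                  peak_amplitude_uV = 150, decay_um = 25,
                  q50_pC = 1.5, slope_pC = 0.15, p_max = 1,
                  latency_mean_ms = 0.8, latency_sd_ms = 0.15,
                  latency_min_ms = 0.4, latency_max_ms = 1.5),
    circuit = list(R_ct = 10e6, C_dl = 1.44e-9, Z_in = 50e6),
    protocol = list(mode = "current",
                    shapes = c("biphasic_anodic_cathodic",
                               "triphasic_anodic_cathodic_anodic"),
                    durations_us = 20,
                    amplitudes = c(42, 63, 84, 105, 126, 147, 168, 189),
                    repetitions = 30, rate = 1),
    recording = list(sample_rate = 20000, noise_rms_uV = 2.4,
                     saturation_limit_mV = 3, lead_in_s = 1),
    detection = list(spontaneous_threshold_k = 4.5, evoked_threshold_k = 4,
                     evoked_window_ms = 1.5, noise_estimator = "sd"),
    fit_impedance = list(enabled = FALSE, I_stim_nA = 560,
                         phase_duration_ms = 2.5, gain = 2,
                         noise_rms_uV = 10),
    fieldsim = list(enabled = FALSE, scenario = "single_vs_reference",
                    block_um = c(150, 150, 50), spacing_um = 2.5,
                    n_rows = 2, n_cols = 2, drive_mV = 100)
  ), class = "run_config")
}

#' Write / read a run configuration (YAML or JSON)
#'
#' @param config A `run_config` (any fully nested list).
#' @param path Destination; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path` invisibly / the parsed `run_config`.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  structure(cfg, class = "run_config")
}

config_objects <- function(config) {
  geometry <- do.call(array_geometry, config$geometry)
  neuron <- do.call(synthetic_neuron, config$neuron)
  circuit <- do.call(electrode_circuit, config$circuit)
  cond_fun <- if (config$protocol$mode == "current") {
    current_protocol_conditions
  } else {
    voltage_protocol_conditions
  }
  conditions <- cond_fun(shapes = config$protocol$shapes,
                         durations_us = config$protocol$durations_us,
                         amplitudes = config$protocol$amplitudes)
  list(geometry = geometry, neuron = neuron, circuit = circuit,
       conditions = conditions)
}

#' Run the pipeline end to end
#'
#' Validates the configuration, then executes the stages: `simulate`
#' (protocol + synthetic session), `detect` (evoked detection on every
#' pulse), `efficiency` (per-condition success table) and `activation`
#' (90% thresholds); optionally `fit_impedance` (round-trip electrode-
#' model fit) and `fieldsim` (scenario solve + probe table). All result
#' tables are written as CSV, the recording as an HDF5 container, and a
#' machine-readable JSON manifest lists every output with per-stage
#' status and timing. Identical configurations yield identical tables.
#'
#' @param config A [default_run_config()]-style configuration.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_end_to_end <- function(config = default_run_config()) {
  t0 <- Sys.time()
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  files <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    tic <- Sys.time()
    result <- tryCatch(list(ok = TRUE, value = fun()),
                       error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    stages[[name]] <<- list(
      name = name,
      status = if (result$ok) "completed" else "failed",
      seconds = as.numeric(difftime(Sys.time(), tic, units = "secs")),
      error = if (result$ok) NULL else result$error
    )
    if (!result$ok) {
      write_manifest()
      stop_mea("stage '%s' failed: %s", name, result$error)
    }
    result$value
  }

  config_path <- file.path(out_dir, "config.json")
  write_run_config(config, config_path)
  files <- c(files, config_path)

  # hash of the scientific configuration only: the output location does
  # not change what a run computes
  hash_cfg <- unclass(config)
  hash_cfg$output_dir <- NULL
  hash_file <- tempfile()
  jsonlite::write_json(hash_cfg, hash_file, auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  write_manifest <- function() {
    manifest <- list(
      config_hash = config_hash,
      files = files,
      stages = unname(stages),
      versions = list(R = as.character(getRversion()),
                      meastim = as.character(utils::packageVersion("meastim"))),
      wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }

  # fail-fast validation: building every waveform catches illegal
  # mode/shape pairings before any simulation runs
  run_stage("validate", function() {
    obj <- config_objects(config)
    list2env(obj, state)
    invisible(TRUE)
  })

  run_stage("simulate", function() {
    protocol <- randomize_protocol(state$conditions,
                                   config$protocol$repetitions,
                                   config$protocol$rate,
                                   seed = derive_seed(config$seed, 1))
    session <- simulate_session(
      protocol, state$neuron, state$geometry, state$circuit,
      seed = derive_seed(config$seed, 2),
      noise_rms_uV = config$recording$noise_rms_uV,
      sample_rate = config$recording$sample_rate,
      saturation_limit_mV = config$recording$saturation_limit_mV,
      lead_in_s = config$recording$lead_in_s
    )
    state$session <- session
    p <- file.path(out_dir, "protocol.csv")
    write_protocol_table(protocol, p)
    b <- file.path(out_dir, "recording.h5")
    write_block(session$block, b, ground_truth = session$ground_truth,
                config = unclass(config))
    g <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(session$ground_truth, g, row.names = FALSE)
    files <<- c(files, p, b, g)
    invisible(TRUE)
  })

  run_stage("detect", function() {
    dc <- config$detection
    state$det_config <- detection_config(
      spontaneous_threshold_k = dc$spontaneous_threshold_k,
      evoked_threshold_k = dc$evoked_threshold_k,
      evoked_window_ms = dc$evoked_window_ms,
      noise_estimator = dc$noise_estimator
    )
    state$eff <- efficiency_table(state$session, state$det_config)
    invisible(TRUE)
  })

  run_stage("efficiency", function() {
    p <- file.path(out_dir, "efficiency.csv")
    utils::write.csv(as.data.frame(state$eff), p, row.names = FALSE)
    files <<- c(files, p)
    invisible(TRUE)
  })

  run_stage("activation", function() {
    act <- activation_threshold(state$eff, efficiency = 0.9)
    p1 <- file.path(out_dir, "activation_curves.csv")
    p2 <- file.path(out_dir, "activation_thresholds.csv")
    utils::write.csv(act$curves, p1, row.names = FALSE)
    utils::write.csv(act$thresholds, p2, row.names = FALSE)
    files <<- c(files, p1, p2)
    invisible(TRUE)
  })

  if (isTRUE(config$fit_impedance$enabled)) {
    run_stage("fit_impedance", function() {
      fi <- config$fit_impedance
      rec <- forward_transient(state$circuit, fi$I_stim_nA * 1e-9,
                               fi$phase_duration_ms * 1e-3,
                               sample_rate = config$recording$sample_rate,
                               gain = fi$gain,
                               noise_rms_V = fi$noise_rms_uV * 1e-6,
                               seed = derive_seed(config$seed, 3))
      fit <- fit_transient(rec, Z_in = state$circuit$Z_in)
      p <- file.path(out_dir, "impedance_fit.csv")
      utils::write.csv(data.frame(
        electrode_id = 1, R_ct_hat = fit$R_ct_hat, C_dl_hat = fit$C_dl_hat,
        residual_rms = fit$residual_rms, converged = fit$converged
      ), p, row.names = FALSE)
      files <<- c(files, p)
      invisible(TRUE)
    })
  }

  if (isTRUE(config$fieldsim$enabled)) {
    run_stage("fieldsim", function() {
      fs <- config$fieldsim
      dom <- build_domain(block_um = fs$block_um, spacing_um = fs$spacing_um,
                          n_rows = fs$n_rows, n_cols = fs$n_cols)
      tab <- compare_configurations(dom, scenarios = fs$scenario,
                                    drive_mV = fs$drive_mV)
      p <- file.path(out_dir, "fieldsim_probes.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      files <<- c(files, p)
      invisible(TRUE)
    })
  }

  invisible(write_manifest())
}
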