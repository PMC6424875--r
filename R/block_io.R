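BLOCK_SCHEMA_VERSION <- 1L

#' Persist a recording block to an HDF5 container
#'
#' Layout: `/traces` (electrodes x samples, float32 uV), `/geometry`
#' (positions table plus scalars), `/ground_truth` (optional table),
#' `/config` (JSON string), `/seed`, `/sample_rate`, `/noise_rms_uV`,
#' `/saturation_limit_uV`, `/schema_version`. Traces are stored in single
#' precision; reading back and re-writing round-trips losslessly.
#'
#' @param block A `recording_block`.
#' @param path Output `.h5` path (overwritten).
#' @param ground_truth Optional ground-truth data frame (e.g. from a
#'   `stim_session`).
#' @param config Optional run configuration (serialized as JSON).
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path, ground_truth = NULL, config = NULL) {
  stopifnot(inherits(block, "recording_block"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createDataset(path, "traces", dims = dim(block$traces),
                         H5type = "H5T_IEEE_F32LE",
                         chunk = c(nrow(block$traces),
                                   min(ncol(block$traces), 65536)),
                         level = 4)
  rhdf5::h5write(block$traces, path, "traces")
  rhdf5::h5write(block$geometry$positions, path, "geometry")
  rhdf5::h5write(c(block$geometry$n_rows, block$geometry$n_cols), path, "geometry_grid")
  rhdf5::h5write(block$geometry$pitch_um, path, "pitch_um")
  rhdf5::h5write(block$geometry$electrode_size_um, path, "electrode_size_um")
  rhdf5::h5write(block$sample_rate, path, "sample_rate")
  rhdf5::h5write(block$noise_rms_uV, path, "noise_rms_uV")
  rhdf5::h5write(block$saturation_limit_uV, path, "saturation_limit_uV")
  rhdf5::h5write(block$seed, path, "seed")
  rhdf5::h5write(BLOCK_SCHEMA_VERSION, path, "schema_version")
  if (!is.null(ground_truth)) rhdf5::h5write(ground_truth, path, "ground_truth")
  if (!is.null(config)) {
    rhdf5::h5write(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA)),
                   path, "config")
  }
  invisible(path)
}

#' Read a recording block from an HDF5 container
#'
#' Inverse of [write_block()]. A missing `/ground_truth` group leaves the
#' ground truth absent (`NULL`); files without the expected schema raise
#' an explicit format error.
#'
#' @param path Container path.
#' @return List with `block`, `ground_truth` (or NULL) and `config` (or
#'   NULL).
#' @export
read_block <- function(path) {
  if (!file.exists(path)) stop_mea("no such file: %s", path)
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE)$name,
                       error = function(e) {
                         stop_mea("'%s' is not a readable HDF5 recording-block container", path)
                       })
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  need <- c("traces", "geometry", "sample_rate", "schema_version")
  if (!all(need %in% contents)) {
    stop_mea("'%s' lacks required groups (%s): not a recording-block container",
             path, paste(setdiff(need, contents), collapse = ", "))
  }
  ver <- as.integer(rhdf5::h5read(path, "schema_version"))
  if (ver > BLOCK_SCHEMA_VERSION) {
    stop_mea("container schema version %d not supported (this build reads <= %d)",
             ver, BLOCK_SCHEMA_VERSION)
  }
  # rhdf5 returns columns/vectors as 1-d arrays; strip the dim attributes
  drop_dims <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) as.vector(col) else col)
    df
  }
  traces <- rhdf5::h5read(path, "traces")
  pos <- drop_dims(as.data.frame(rhdf5::h5read(path, "geometry")))
  grid <- rhdf5::h5read(path, "geometry_grid")
  geometry <- array_geometry(grid[1], grid[2],
                             as.numeric(rhdf5::h5read(path, "pitch_um")),
                             as.numeric(rhdf5::h5read(path, "electrode_size_um")))
  geometry$positions <- as.data.frame(pos)
  block <- new_recording_block(
    geometry,
    as.numeric(rhdf5::h5read(path, "sample_rate")),
    traces,
    as.numeric(rhdf5::h5read(path, "noise_rms_uV")),
    as.numeric(rhdf5::h5read(path, "saturation_limit_uV")),
    as.numeric(rhdf5::h5read(path, "seed"))
  )
  gt <- if ("ground_truth" %in% contents) {
    drop_dims(as.data.frame(rhdf5::h5read(path, "ground_truth")))
  } else NULL
  config <- if ("config" %in% contents) {
    jsonlite::fromJSON(as.character(rhdf5::h5read(path, "config")))
  } else NULL
  list(block = block, ground_truth = gt, config = config)
}
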