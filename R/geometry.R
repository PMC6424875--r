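#' Planar HD-MEA electrode geometry
#'
#' Regular grid of planar electrodes, defaulting to the HD-MEA layout:
#' 5 x 9 um electrodes at a pitch of 17.5 um. Positions are electrode
#' centers in um, row-major.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch_um Center-to-center pitch in um (default 17.5).
#' @param electrode_size_um Electrode width and height in um (default
#'   c(5, 9)).
#' @return Object of class `array_geometry` with a `positions` data frame
#'   (electrode, row, col, x, y).
#' @export
array_geometry <- function(n_rows = 6, n_cols = 6, pitch_um = 17.5,
                           electrode_size_um = c(5, 9)) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_um > 0)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  positions <- data.frame(
    electrode = seq_len(nrow(grid)),
    row = grid$row, col = grid$col,
    x = (grid$col - 1) * pitch_um,
    y = (grid$row - 1) * pitch_um
  )
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
                 electrode_size_um = electrode_size_um, positions = positions),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d x %d electrodes, pitch %g um, electrode %g x %g um\n",
              x$n_rows, x$n_cols, x$pitch_um,
              x$electrode_size_um[1], x$electrode_size_um[2]))
  invisible(x)
}

n_electrodes <- function(geometry) nrow(geometry$positions)

# Distances (um) from every electrode center to a point c(x, y).
electrode_distances <- function(geometry, point) {
  sqrt((geometry$positions$x - point[1])^2 + (geometry$positions$y - point[2])^2)
}

point_in_array <- function(geometry, point, margin = NULL) {
  margin <- margin %||% geometry$pitch_um / 2
  p <- geometry$positions
  point[1] >= min(p$x) - margin && point[1] <= max(p$x) + margin &&
    point[2] >= min(p$y) - margin && point[2] <= max(p$y) + margin
}
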