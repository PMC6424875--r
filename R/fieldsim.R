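#' Build the electrostatic simulation domain
#'
#' Discretizes an electrolyte block above a planar electrode array on a
#' uniform grid. Defaults reproduce the simulated HD-MEA scene: a
#' 500 x 500 x 100 um saline block (conductivity 0.7 S/m) over a 6 x 6
#' block of 5 x 9 um electrodes at 17.5 um pitch, with four 5 x 245 um
#' reference strips around the array on the z = 0 plane. Electrode and
#' strip rectangles are mapped to the nearest grid nodes; the grid must
#' resolve the 5 um electrode edge with at least two nodes.
#'
#' @param block_um Block dimensions c(x, y, z) in um.
#' @param spacing_um Grid spacing in um (default 2.5).
#' @param sigma_S_per_m Electrolyte conductivity (default 0.7 S/m; enters
#'   reporting only - the potential of a uniform conductor is
#'   conductivity-independent).
#' @param n_rows,n_cols Electrode grid (default 6 x 6 = 36).
#' @param pitch_um Electrode pitch (default 17.5).
#' @param electrode_size_um Electrode x/y extent (default c(5, 9)).
#' @param strip_size_um Reference-strip extent along its short/long axis
#'   (default c(5, 245)).
#' @param strip_offset_um Gap between array bounding box and strips
#'   (default 30 um).
#' @param electrode_centers_um Optional n x 2 matrix of electrode centers
#'   overriding the regular grid (used e.g. for symmetric test layouts).
#' @return Object of class `field_domain`.
#' @export
build_domain <- function(block_um = c(500, 500, 100), spacing_um = 2.5,
                         sigma_S_per_m = 0.7, n_rows = 6, n_cols = 6,
                         pitch_um = 17.5, electrode_size_um = c(5, 9),
                         strip_size_um = c(5, 245), strip_offset_um = 30,
                         electrode_centers_um = NULL) {
  if (spacing_um > min(electrode_size_um)) {
    stop_mea("grid spacing %g um does not resolve the %g um electrode edge (need >= 2 nodes)",
             spacing_um, min(electrode_size_um))
  }
  x <- seq(0, block_um[1], by = spacing_um)
  y <- seq(0, block_um[2], by = spacing_um)
  z <- seq(0, block_um[3], by = spacing_um)
  nx <- length(x); ny <- length(y); nz <- length(z)

  if (is.null(electrode_centers_um)) {
    cx0 <- block_um[1] / 2 - (n_cols - 1) * pitch_um / 2
    cy0 <- block_um[2] / 2 - (n_rows - 1) * pitch_um / 2
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    centers <- cbind(cx0 + (grid$col - 1) * pitch_um,
                     cy0 + (grid$row - 1) * pitch_um)
  } else {
    centers <- as.matrix(electrode_centers_um)
  }

  rect_nodes <- function(cx, cy, wx, wy) {
    ix <- which(x >= cx - wx / 2 - 1e-9 & x <= cx + wx / 2 + 1e-9)
    iy <- which(y >= cy - wy / 2 - 1e-9 & y <= cy + wy / 2 + 1e-9)
    if (length(ix) < 2 || length(iy) < 2) {
      stop_mea("patch at (%g, %g) under-resolved by the grid", cx, cy)
    }
    g <- expand.grid(i = ix, j = iy)
    # linear index on the x-fastest grid, z layer k = 1
    (g$i - 1) + nx * (g$j - 1) + 1
  }

  electrodes <- lapply(seq_len(nrow(centers)), function(e) {
    rect_nodes(centers[e, 1], centers[e, 2],
               electrode_size_um[1], electrode_size_um[2])
  })

  xmin <- min(centers[, 1]) - electrode_size_um[1] / 2
  xmax <- max(centers[, 1]) + electrode_size_um[1] / 2
  ymin <- min(centers[, 2]) - electrode_size_um[2] / 2
  ymax <- max(centers[, 2]) + electrode_size_um[2] / 2
  ycen <- (ymin + ymax) / 2; xcen <- (xmin + xmax) / 2
  off <- strip_offset_um + strip_size_um[1] / 2
  strips <- list(
    left   = rect_nodes(xmin - off, ycen, strip_size_um[1], strip_size_um[2]),
    right  = rect_nodes(xmax + off, ycen, strip_size_um[1], strip_size_um[2]),
    bottom = rect_nodes(xcen, ymin - off, strip_size_um[2], strip_size_um[1]),
    top    = rect_nodes(xcen, ymax + off, strip_size_um[2], strip_size_um[1])
  )

  structure(
    list(x = x, y = y, z = z, nx = nx, ny = ny, nz = nz,
         spacing_um = spacing_um, block_um = block_um,
         sigma_S_per_m = sigma_S_per_m,
         electrodes = electrodes, electrode_centers = centers,
         strips = strips),
    class = "field_domain"
  )
}

#' @export
print.field_domain <- function(x, ...) {
  cat(sprintf("<field_domain> %g x %g x %g um @ %g um (%d nodes), %d electrodes, %d reference strips\n",
              x$block_um[1], x$block_um[2], x$block_um[3], x$spacing_um,
              x$nx * x$ny * x$nz, length(x$electrodes), length(x$strips)))
  invisible(x)
}

#' Electrode boundary configuration for a stimulation scenario
#'
#' Maps a stimulation scenario to Dirichlet boundary values on the z = 0
#' plane: `single_vs_reference` drives one electrode at `+drive` against
#' the grounded reference strips; `opposite_pair` drives two neighboring
#' electrodes at `+drive` and `-drive`; `grounded_neighbor` drives one
#' electrode with its neighbor held at ground. All other array electrodes
#' are floating and treated as part of the insulating plane (a true
#' floating conductor carries no defined potential and is not modeled).
#' The reference strips are always grounded.
#'
#' @param domain A [build_domain()].
#' @param scenario One of `"single_vs_reference"`, `"opposite_pair"`,
#'   `"grounded_neighbor"`, or `"custom"`.
#' @param drive_mV Drive amplitude (default 100, the positive phase of the
#'   +/-100 mV biphasic waveform; by linearity the negative phase is the
#'   sign flip).
#' @param e1,e2 Electrode indices; default to the central horizontal
#'   neighbor pair.
#' @param values For `"custom"`: named numeric vector of drive values
#'   (mV) indexed by electrode.
#' @return List of Dirichlet node indices and values, class
#'   `electrode_boundary_config`.
#' @export
scenario_config <- function(domain,
                            scenario = c("single_vs_reference", "opposite_pair",
                                         "grounded_neighbor", "custom"),
                            drive_mV = 100, e1 = NULL, e2 = NULL, values = NULL) {
  scenario <- match.arg(scenario)
  n_e <- length(domain$electrodes)
  if (is.null(e1) || is.null(e2)) {
    ctr <- colMeans(domain$electrode_centers)
    d <- sqrt(rowSums((domain$electrode_centers -
                         matrix(ctr, n_e, 2, byrow = TRUE))^2))
    e1 <- e1 %||% which.min(d)
    # companion electrode: nearest same-row neighbor on the +x side (so
    # the -x direction from e1 is the far-field side in every scenario),
    # falling back to the nearest same-row neighbor
    cand <- which(abs(domain$electrode_centers[, 2] -
                        domain$electrode_centers[e1, 2]) < 1e-9)
    cand <- setdiff(cand, e1)
    right <- cand[domain$electrode_centers[cand, 1] >
                    domain$electrode_centers[e1, 1]]
    pick <- if (length(right)) right else cand
    e2 <- e2 %||% pick[which.min(abs(domain$electrode_centers[pick, 1] -
                                       domain$electrode_centers[e1, 1]))]
  }
  drive <- switch(scenario,
    single_vs_reference = stats::setNames(drive_mV, e1),
    opposite_pair = stats::setNames(c(drive_mV, -drive_mV), c(e1, e2)),
    grounded_neighbor = stats::setNames(c(drive_mV, 0), c(e1, e2)),
    custom = {
      if (is.null(values)) stop_mea("custom scenario requires 'values'")
      values
    }
  )
  nodes <- integer(0); vals <- numeric(0)
  for (nm in names(drive)) {
    e <- as.integer(nm)
    nodes <- c(nodes, domain$electrodes[[e]])
    vals <- c(vals, rep(drive[[nm]], length(domain$electrodes[[e]])))
  }
  for (s in domain$strips) {
    nodes <- c(nodes, s)
    vals <- c(vals, rep(0, length(s)))
  }
  structure(list(scenario = scenario, e1 = e1, e2 = e2, drive_mV = drive_mV,
                 nodes = nodes, values = vals),
            class = "electrode_boundary_config")
}

#' Solve the quasi-static potential over the domain
#'
#' Finite-difference solution of Laplace's equation (uniform conductivity,
#' charge-free electrolyte) with Dirichlet values on driven/grounded
#' patches and reference strips and insulating (zero-normal-derivative)
#' conditions everywhere else, by red-black successive over-relaxation.
#' The field magnitude |E| = sqrt(Ex^2 + Ey^2 + Ez^2) is computed from
#' central differences of the converged potential.
#'
#' @param domain A [build_domain()].
#' @param config A [scenario_config()].
#' @param tol Relative convergence tolerance on the SOR update (default
#'   1e-8).
#' @param max_iter Iteration cap; non-convergence is an error reporting
#'   the residual.
#' @param omega Over-relaxation factor; default near-optimal for the grid.
#' @return Object of class `field_solution`: potential `V` (mV) and
#'   `E_norm` (V/m) as 3-D arrays, plus solver diagnostics.
#' @export
solve_laplace <- function(domain, config, tol = 1e-8, max_iter = 200000,
                          omega = NULL) {
  stopifnot(inherits(domain, "field_domain"),
            inherits(config, "electrode_boundary_config"))
  if (!length(config$nodes)) stop_mea("boundary configuration drives no patch")
  n <- domain$nx * domain$ny * domain$nz
  v0 <- numeric(n)
  dir <- logical(n)
  v0[config$nodes] <- config$values
  dir[config$nodes] <- TRUE
  omega <- omega %||% (2 / (1 + sin(pi / max(domain$nx, domain$ny, domain$nz))))
  sol <- sor_laplace(v0, dir, domain$nx, domain$ny, domain$nz,
                     omega, tol, as.integer(max_iter))
  if (!sol$converged) {
    stop_mea("field solver did not converge in %d iterations (last relative update %.3g, residual %.3g)",
             max_iter, sol$max_delta, sol$residual)
  }
  V <- array(sol$v, dim = c(domain$nx, domain$ny, domain$nz))
  E <- field_norm(V, domain$spacing_um)
  structure(
    list(domain = domain, config = config, V = V, E_norm = E,
         iterations = sol$iterations, residual = sol$residual,
         dirichlet = array(dir, dim = dim(V))),
    class = "field_solution"
  )
}

# |E| in V/m from V in mV on a grid spaced in um: 1 mV/um = 1000 V/m.
# Central differences inside, one-sided at the faces.
field_norm <- function(V, spacing_um) {
  d <- dim(V)
  grad_along <- function(A, axis) {
    n <- dim(A)[axis]
    idx <- function(shift) {
      i <- pmin(pmax(seq_len(n) + shift, 1), n)
      switch(axis, A[i, , , drop = FALSE], A[, i, , drop = FALSE], A[, , i, drop = FALSE])
    }
    den <- array(2, dim = d)
    edge1 <- switch(axis, den[1, , ] <- 1, den[, 1, ] <- 1, den[, , 1] <- 1)
    edgeN <- switch(axis, den[n, , ] <- 1, den[, n, ] <- 1, den[, , n] <- 1)
    (idx(1) - idx(-1)) / (den * spacing_um)
  }
  gx <- grad_along(V, 1); gy <- grad_along(V, 2); gz <- grad_along(V, 3)
  1000 * sqrt(gx^2 + gy^2 + gz^2)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %s: %d iterations, residual %.2g, V in [%.3g, %.3g] mV\n",
              x$config$scenario, x$iterations, x$residual, min(x$V), max(x$V)))
  invisible(x)
}

#' Export a field solution to an HDF5 container
#'
#' Layout: `/potential` (mV) and `/efnorm` (V/m) as 3-D float arrays and
#' `/grid/x`, `/grid/y`, `/grid/z` (um), plus the scenario name.
#'
#' @param solution A [solve_laplace()] result.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_field_solution <- function(solution, path) {
  stopifnot(inherits(solution, "field_solution"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(solution$V, path, "potential")
  rhdf5::h5write(solution$E_norm, path, "efnorm")
  rhdf5::h5createGroup(path, "grid")
  rhdf5::h5write(solution$domain$x, path, "grid/x")
  rhdf5::h5write(solution$domain$y, path, "grid/y")
  rhdf5::h5write(solution$domain$z, path, "grid/z")
  rhdf5::h5write(solution$config$scenario, path, "scenario")
  invisible(path)
}

#' Sample potential and field magnitude at a point
#'
#' Trilinear interpolation of V (mV) and |E| (V/m) at a position in um.
#'
#' @param solution A [solve_laplace()] result.
#' @param position_um Numeric c(x, y, z) inside the domain.
#' @return List with `V_mV` and `E_norm_V_per_m`.
#' @export
probe <- function(solution, position_um) {
  stopifnot(inherits(solution, "field_solution"))
  dom <- solution$domain
  p <- position_um
  if (p[1] < dom$x[1] || p[1] > dom$x[dom$nx] ||
      p[2] < dom$y[1] || p[2] > dom$y[dom$ny] ||
      p[3] < dom$z[1] || p[3] > dom$z[dom$nz]) {
    stop_mea("probe position (%g, %g, %g) um outside the domain", p[1], p[2], p[3])
  }
  interp <- function(A) {
    h <- dom$spacing_um
    f <- (p - c(dom$x[1], dom$y[1], dom$z[1])) / h
    i0 <- pmin(floor(f), c(dom$nx, dom$ny, dom$nz) - 2) + 1
    w <- f - (i0 - 1)
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      acc <- acc + wt * A[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    acc
  }
  list(V_mV = interp(solution$V), E_norm_V_per_m = interp(solution$E_norm))
}

#' Compare stimulation configurations at shared probes
#'
#' Solves each scenario on the same domain and tabulates probe voltage
#' and field magnitude side by side, plus a lateral artifact-extent
#' proxy: the largest lateral distance from the driven electrode at which
#' |V| (at probe height) still exceeds a fraction of the drive.
#'
#' @param domain A [build_domain()].
#' @param scenarios Character vector of scenario names.
#' @param probes List of probe positions (each c(x, y, z) um); defaults
#'   to 1 um above the plane, left and right of the driven electrode.
#' @param drive_mV Drive amplitude.
#' @param extent_fraction Fraction of the drive defining the extent proxy
#'   (default 0.1).
#' @param tol,max_iter Solver controls.
#' @return Data frame with one row per scenario x probe, plus
#'   `extent_um` per scenario.
#' @export
compare_configurations <- function(domain,
                                   scenarios = c("single_vs_reference",
                                                 "opposite_pair",
                                                 "grounded_neighbor"),
                                   probes = NULL, drive_mV = 100,
                                   extent_fraction = 0.1,
                                   tol = 1e-8, max_iter = 200000) {
  cfg1 <- scenario_config(domain, scenarios[1], drive_mV)
  c1 <- domain$electrode_centers[cfg1$e1, ]
  halfx <- 2.5
  probes <- probes %||% list(
    left = c(c1[1] - halfx - 2.5, c1[2], 1),
    right = c(c1[1] + halfx + 2.5, c1[2], 1)
  )
  if (is.null(names(probes))) names(probes) <- paste0("p", seq_along(probes))
  rows <- list()
  for (sc in scenarios) {
    cfg <- scenario_config(domain, sc, drive_mV)
    sol <- solve_laplace(domain, cfg, tol = tol, max_iter = max_iter)
    # lateral |V| profile at probe height along -x from the driven
    # electrode, i.e. away from the companion electrode, where the far
    # field of the configuration determines how far the artifact spreads
    xs <- domain$x[domain$x <= c1[1]]
    vline <- vapply(xs, function(xx) {
      probe(sol, c(xx, c1[2], 1))$V_mV
    }, 0)
    above <- which(abs(vline) >= extent_fraction * drive_mV)
    extent <- if (length(above)) c1[1] - min(xs[above]) else 0
    for (pn in names(probes)) {
      pr <- probe(sol, probes[[pn]])
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc, probe = pn,
        x_um = probes[[pn]][1], y_um = probes[[pn]][2], z_um = probes[[pn]][3],
        V_mV = pr$V_mV, E_norm_V_per_m = pr$E_norm_V_per_m,
        extent_um = extent, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
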