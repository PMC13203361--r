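# Eulerian advection-diffusion of the cell-concentration plume in the chamber
# mid-plane (first-order upwind finite volume + explicit diffusion) and its
# Lagrangian single-cell twin.

#' Microfluidic chamber geometry
#'
#' @param length Chamber length along the flow (m, default 32 mm).
#' @param width Chamber width (m, default 14 mm).
#' @param height Chamber height (m, default 175 um); metadata only, the
#'   solver is a depth-averaged 2-D mid-plane model.
#' @param inlet_band y-interval of the inlet stripe carrying labelled cells
#'   (m); default a 2 mm band centred on the flow axis.
#' @return An object of class \code{chamber_spec}.
#' @export
chamber_spec <- function(length = 32e-3, width = 14e-3, height = 175e-6,
                         inlet_band = NULL) {
  stopifnot(length > 0, width > 0, height > 0)
  if (is.null(inlet_band)) inlet_band <- width / 2 + c(-1e-3, 1e-3)
  stopifnot(inlet_band[1] >= 0, inlet_band[2] <= width,
            inlet_band[1] < inlet_band[2])
  structure(list(length = length, width = width, height = height,
                 inlet_band = inlet_band),
            class = "chamber_spec")
}

# Cell-centred grid over the mid-plane.
chamber_grid <- function(chamber, spacing) {
  nx <- max(2L, round(chamber$length / spacing))
  ny <- max(2L, round(chamber$width / spacing))
  list(x = (seq_len(nx) - 0.5) * spacing, y = (seq_len(ny) - 0.5) * spacing,
       nx = nx, ny = ny, h = spacing)
}

#' Transport solver parameters
#'
#' @param diffusivity_D Effective diffusivity (m^2/s, default 1e-10). Chosen
#'   well above the Stokes-Einstein value of a 10 um cell purely as
#'   regularization and to give the plume a realistic width.
#' @param dx Grid spacing (m, default 0.1 mm).
#' @param dt Time step (s); \code{NULL} picks \code{cfl} times the stability
#'   bound.
#' @param t_end Simulated transient length (s, default 180 s, the 0-3 min
#'   observation window of the recordings; the plume is established at the
#'   magnet station well within it at 0.2 mm/s).
#' @param cfl Safety factor on the advective-diffusive stability bound.
#' @param inlet_conc Inlet concentration on the band (mol/m^3, default 1).
#' @return An object of class \code{transport_params}.
#' @export
transport_params <- function(diffusivity_D = 1e-10, dx = 1e-4, dt = NULL,
                             t_end = 180, cfl = 0.5, inlet_conc = 1) {
  stopifnot(diffusivity_D >= 0, dx > 0, t_end > 0, cfl > 0, cfl <= 1,
            inlet_conc >= 0)
  structure(list(diffusivity_D = diffusivity_D, dx = dx, dt = dt,
                 t_end = t_end, cfl = cfl, inlet_conc = inlet_conc),
            class = "transport_params")
}

#' Magnetophoretic cell-velocity field on the transport grid
#'
#' \code{v_p = (dUx, 0) + m grad|B| / (6 pi eta r_p)} per node: uniform plug
#' flow plus the local slip set by the force balance.
#'
#' @param chamber A \code{\link{chamber_spec}}.
#' @param fg A \code{\link{field_grid}} on the same chamber (or \code{NULL}
#'   for no magnet).
#' @param cell A \code{\link{cell_model}}.
#' @param fluid A \code{\link{fluid_spec}}.
#' @param spacing Grid spacing (m); must match \code{fg} when given.
#' @return An object of class \code{velocity_field}: coordinate vectors and
#'   nx x ny matrices \code{vx}, \code{vy} (m/s).
#' @export
velocity_field <- function(chamber, fg = NULL, cell, fluid, spacing = 1e-4) {
  g <- chamber_grid(chamber, spacing)
  m <- magnetic_moment(cell)
  drag <- 6 * pi * fluid$viscosity_eta * (cell$cell_diameter / 2)
  vx <- matrix(fluid$inlet_speed_dUx, g$nx, g$ny)
  vy <- matrix(0, g$nx, g$ny)
  if (!is.null(fg) && m > 0) {
    if (abs(fg$spacing - spacing) > 1e-12 || length(fg$x) != g$nx)
      stop("field_grid spacing does not match the transport grid")
    vx <- vx + m * fg$gradBx / drag
    vy <- vy + m * fg$gradBy / drag
  }
  structure(list(x = g$x, y = g$y, nx = g$nx, ny = g$ny, h = g$h,
                 vx = vx, vy = vy, chamber = chamber),
            class = "velocity_field")
}

stability_dt <- function(vel, D) {
  h <- vel$h
  denom <- max(abs(vel$vx)) / h + max(abs(vel$vy)) / h + 4 * D / h^2
  if (denom == 0) Inf else 1 / denom
}

#' Solve the plume transport equation
#'
#' Conservative first-order upwind finite-volume advection with explicit
#' central diffusion on a cell-centred grid. Boundary conditions: Dirichlet
#' inlet concentration on the inlet band at x = 0 (zero elsewhere on the
#' inlet face), upwind outflow at x = length, no-flux side walls (cells
#' accumulate against the magnet-side wall). Per-step mass bookkeeping
#' (influx minus outflux) is recorded.
#'
#' @param chamber A \code{\link{chamber_spec}}.
#' @param params A \code{\link{transport_params}}.
#' @param vel A \code{\link{velocity_field}} on the same grid.
#' @param snapshot_times Times (s) at which concentration snapshots are kept;
#'   default 10 evenly spaced plus the final time.
#' @param c0 Optional initial concentration matrix (nx x ny); default zero
#'   (the chamber starts filled with clean buffer).
#' @return An object of class \code{transport_solution}: snapshot list
#'   \code{conc} with \code{times}, the \code{final} field, the grid, and a
#'   \code{mass} data.frame (time, mass, influx rate, outflux rate).
#' @export
solve_transport <- function(chamber, params, vel, snapshot_times = NULL,
                            c0 = NULL) {
  h <- vel$h
  nx <- vel$nx; ny <- vel$ny
  D <- params$diffusivity_D
  dt_max <- stability_dt(vel, D)
  dt <- params$dt
  if (is.null(dt)) dt <- params$cfl * dt_max
  if (dt > dt_max)
    stop(sprintf("dt = %.4g s violates the stability bound; use dt <= %.4g s",
                 dt, dt_max))
  nsteps <- ceiling(params$t_end / dt)
  dt <- params$t_end / nsteps
  if (is.null(snapshot_times))
    snapshot_times <- seq(0, params$t_end, length.out = 11)[-1]
  snap_steps <- unique(pmax(1L, pmin(nsteps, round(snapshot_times / dt))))

  # face velocities (x-faces: (nx+1) x ny; y-faces: nx x (ny+1))
  ux <- rbind(vel$vx[1, ], (vel$vx[-nx, ] + vel$vx[-1, ]) / 2, vel$vx[nx, ])
  uy <- cbind(0, (vel$vy[, -ny] + vel$vy[, -1]) / 2, 0)
  uxp <- pmax(ux, 0); uxn <- pmin(ux, 0)
  uyp <- pmax(uy, 0); uyn <- pmin(uy, 0)

  ghost_in <- ifelse(vel$y >= chamber$inlet_band[1] &
                     vel$y <= chamber$inlet_band[2], params$inlet_conc, 0)
  cfield <- if (is.null(c0)) matrix(0, nx, ny) else c0
  stopifnot(all(dim(cfield) == c(nx, ny)), all(cfield >= 0))
  conc <- list(); times <- numeric(0)
  mass_t <- mass_v <- in_v <- out_v <- numeric(nsteps)
  for (step in seq_len(nsteps)) {
    cL <- rbind(ghost_in, cfield)          # upwind donors across x-faces
    cR <- rbind(cfield, 0)                 # no backflow re-entry at outlet
    Fx <- uxp * cL + uxn * cR
    cB <- cbind(0, cfield)
    cT <- cbind(cfield, 0)
    Fy <- uyp * cB + uyn * cT
    Fy[, c(1, ny + 1)] <- 0                # walls: no advective flux
    # explicit diffusion, interior faces only (no-flux boundaries)
    Gx <- matrix(0, nx + 1, ny)
    Gx[2:nx, ] <- -D * (cfield[-1, ] - cfield[-nx, ]) / h
    Gy <- matrix(0, nx, ny + 1)
    Gy[, 2:ny] <- -D * (cfield[, -1] - cfield[, -ny]) / h
    cfield <- cfield - (dt / h) * (Fx[-1, ] - Fx[-(nx + 1), ] +
                                   Fy[, -1] - Fy[, -(ny + 1)] +
                                   Gx[-1, ] - Gx[-(nx + 1), ] +
                                   Gy[, -1] - Gy[, -(ny + 1)])
    mass_t[step] <- step * dt
    mass_v[step] <- sum(cfield) * h^2
    in_v[step] <- sum(Fx[1, ] + Gx[1, ]) * h
    out_v[step] <- sum(Fx[nx + 1, ] + Gx[nx + 1, ]) * h
    if (step %in% snap_steps) {
      conc[[length(conc) + 1]] <- cfield
      times <- c(times, step * dt)
    }
  }
  structure(list(x = vel$x, y = vel$y, h = h, conc = conc, times = times,
                 final = cfield, dt = dt,
                 mass = data.frame(time = mass_t, mass = mass_v,
                                   influx = in_v, outflux = out_v),
                 chamber = chamber, params = params),
            class = "transport_solution")
}

#' @export
print.transport_solution <- function(x, ...) {
  cat(sprintf(
    "Transport solution: %d x %d grid (h = %.3g mm), t_end = %.3g s, %d snapshots\n",
    length(x$x), length(x$y), x$h * 1e3, max(x$mass$time), length(x$conc)))
  cat(sprintf("  final total mass %.4g, max c %.4g mol/m^3\n",
              sum(x$final) * x$h^2, max(x$final)))
  invisible(x)
}

# Bilinear interpolation of a node matrix at (px, py); clamped at edges.
interp_grid <- function(xg, yg, M, px, py) {
  h <- xg[2] - xg[1]
  fx <- (px - xg[1]) / h
  fy <- (py - yg[1]) / h
  i <- pmin(pmax(floor(fx), 0), length(xg) - 2)
  j <- pmin(pmax(floor(fy), 0), length(yg) - 2)
  tx <- pmin(pmax(fx - i, 0), 1)
  ty <- pmin(pmax(fy - j, 0), 1)
  i <- i + 1L; j <- j + 1L
  (1 - tx) * (1 - ty) * M[cbind(i, j)] + tx * (1 - ty) * M[cbind(i + 1, j)] +
    (1 - tx) * ty * M[cbind(i, j + 1)] + tx * ty * M[cbind(i + 1, j + 1)]
}

#' Trace a single-cell trajectory through the velocity field
#'
#' Classical 4th-order Runge-Kutta integration of \code{dx/dt = v_p(x)} with
#' bilinear interpolation of the node velocities, until the cell leaves the
#' chamber or \code{t_max} is reached.
#'
#' @param start Length-2 start point (m), inside the chamber.
#' @param vel A \code{\link{velocity_field}}.
#' @param dt Integration step (s).
#' @param t_max Maximum integration time (s).
#' @return An object of class \code{trajectory}: \code{times}, two-column
#'   \code{positions}, and \code{exit_flag} in \code{{"outflow",
#'   "magnet-wall", "interior"}}.
#' @export
trace_trajectory <- function(start, vel, dt = 0.5, t_max = 600) {
  ch <- vel$chamber
  if (start[1] < 0 || start[1] > ch$length || start[2] < 0 ||
      start[2] > ch$width)
    stop("start point outside the chamber")
  f <- function(p) c(interp_grid(vel$x, vel$y, vel$vx, p[1], p[2]),
                     interp_grid(vel$x, vel$y, vel$vy, p[1], p[2]))
  nmax <- ceiling(t_max / dt)
  pos <- matrix(NA_real_, nmax + 1, 2)
  pos[1, ] <- start
  tvec <- (0:nmax) * dt
  flag <- "interior"
  n <- 1
  for (k in seq_len(nmax)) {
    p <- pos[k, ]
    k1 <- f(p); k2 <- f(p + dt / 2 * k1); k3 <- f(p + dt / 2 * k2)
    k4 <- f(p + dt * k3)
    p2 <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    n <- k + 1
    pos[n, ] <- p2
    if (p2[1] >= ch$length) { flag <- "outflow"; break }
    if (p2[2] >= ch$width || p2[2] <= 0) { flag <- "magnet-wall"; break }
  }
  structure(list(times = tvec[seq_len(n)], positions = pos[seq_len(n), ,
                                                           drop = FALSE],
                 exit_flag = flag),
            class = "trajectory")
}

#' Write a trajectory as CSV (t, x_mm, y_mm)
#' @param traj A \code{\link{trace_trajectory}} result.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$times,
                              x_mm = traj$positions[, 1] * 1e3,
                              y_mm = traj$positions[, 2] * 1e3),
                   path, row.names = FALSE)
  invisible(path)
}

# Concentration-weighted lateral centroid at the column nearest station_x.
station_centroid_y <- function(sol, station_x, floor = 1e-9) {
  ix <- which.min(abs(sol$x - station_x))
  col <- sol$final[ix, ]
  if (sum(col) <= floor) return(NA_real_)
  sum(col * sol$y) / sum(col)
}

#' Lateral drift and deflection angle at a downstream station
#'
#' Compares the concentration-weighted lateral centroid of the magnet-on run
#' against the reference (no-magnet) run at the station's grid column. The
#' angle is \code{atan(drift / station_x)} measured from the inlet.
#'
#' @param sol_mag,sol_ref \code{\link{transport_solution}}s on the same grid.
#' @param station_x Downstream station (m), typically the magnet-axis x.
#' @param floor Concentration-sum floor below which the plume is flagged
#'   not measurable.
#' @return List with \code{drift} (m), \code{angle} (rad),
#'   \code{measurable} (logical).
#' @export
deflection_metric <- function(sol_mag, sol_ref, station_x, floor = 1e-9) {
  if (length(sol_mag$x) != length(sol_ref$x))
    stop("runs must share the same grid")
  y1 <- station_centroid_y(sol_mag, station_x, floor)
  y0 <- station_centroid_y(sol_ref, station_x, floor)
  if (is.na(y1) || is.na(y0))
    return(list(drift = NA_real_, angle = NA_real_, measurable = FALSE))
  drift <- y1 - y0
  list(drift = drift, angle = atan(drift / station_x), measurable = TRUE)
}

# Centroid of the near-wall accumulation zone: concentration above 50% of the
# band maximum within band_width of the magnet-side wall.
accumulation_centroid <- function(sol, band_width = 1e-3, rel_thresh = 0.5,
                                  floor = 1e-9) {
  ny <- length(sol$y)
  jband <- which(sol$y >= sol$chamber$width - band_width)
  band <- sol$final[, jband, drop = FALSE]
  if (max(band) <= floor) return(NULL)
  keep <- band >= rel_thresh * max(band)
  w <- band * keep
  xs <- matrix(sol$x, nrow(band), ncol(band))
  ys <- matrix(sol$y[jband], nrow(band), ncol(band), byrow = TRUE)
  c(sum(w * xs) / sum(w), sum(w * ys) / sum(w))
}

#' Transmission coefficient of the accumulation zone to a magnet shift
#'
#' Ratio of the displacement of the near-magnet accumulation centroid to the
#' magnet displacement, projected on the shift direction. The observed ratio
#' is roughly 1:1, the basis of precision remote positioning.
#'
#' @param sol_base,sol_shift \code{\link{transport_solution}}s for the base
#'   and shifted magnet placements (same scenario otherwise).
#' @param shift Length-2 magnet displacement vector (m).
#' @param band_width Width of the wall band scanned for accumulation (m).
#' @return List with \code{ratio} (dimensionless), \code{centroid_base},
#'   \code{centroid_shift}, and \code{flagged} (TRUE when degenerate: zero
#'   shift or no accumulation detected).
#' @export
transmission_coefficient <- function(sol_base, sol_shift, shift,
                                     band_width = 1e-3) {
  smag <- sqrt(sum(shift^2))
  if (smag == 0)
    return(list(ratio = NA_real_, flagged = TRUE, reason = "zero shift"))
  c0 <- accumulation_centroid(sol_base, band_width)
  c1 <- accumulation_centroid(sol_shift, band_width)
  if (is.null(c0) || is.null(c1))
    return(list(ratio = NA_real_, flagged = TRUE,
                reason = "no accumulation detected"))
  ratio <- sum((c1 - c0) * shift / smag) / smag
  list(ratio = ratio, centroid_base = c0, centroid_shift = c1,
       flagged = FALSE)
}
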