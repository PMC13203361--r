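# One-call forward simulation of a scenario; the field grid depends only on
# magnet + placement + grid, so it can be reused across loadings.

#' Run the forward magnetophoretic transport model for one scenario
#'
#' Convenience wrapper: field grid (unless supplied), velocity field, and
#' transport solve. With \code{magnet = NULL} (or zero loading) the run is
#' the no-field reference.
#'
#' @param chamber A \code{\link{chamber_spec}}.
#' @param magnet A \code{\link{magnet_spec}} or \code{NULL} for no magnet.
#' @param placement A \code{\link{magnet_placement}}.
#' @param cell A \code{\link{cell_model}}.
#' @param fluid A \code{\link{fluid_spec}}.
#' @param params A \code{\link{transport_params}}.
#' @param fg Optional precomputed \code{\link{field_grid}} (must match the
#'   grid spacing).
#' @param snapshot_times Passed to \code{\link{solve_transport}}.
#' @return List with the \code{\link{transport_solution}} (\code{sol}), the
#'   \code{\link{velocity_field}} (\code{vel}) and the field grid (\code{fg},
#'   possibly NULL).
#' @export
simulate_scenario <- function(chamber, magnet, placement, cell, fluid,
                              params, fg = NULL, snapshot_times = NULL) {
  if (!is.null(magnet) && is.null(fg) && magnetic_moment(cell) > 0)
    fg <- field_grid(magnet, placement, chamber, spacing = params$dx)
  vel <- velocity_field(chamber, fg, cell, fluid, spacing = params$dx)
  sol <- solve_transport(chamber, params, vel, snapshot_times)
  list(sol = sol, vel = vel, fg = fg)
}

#' Deflection sweep over magnetic diameter and fluid speed
#'
#' Runs the forward model on a grid of equivalent magnetic diameters and
#' inlet speeds (defaults: d_mag 1.0-1.6 um at 0.2 and 0.5 mm/s, the
#' loading/speed design space of the remote-guiding study) and records the
#' lateral drift and deflection angle at the magnet-axis station.
#'
#' @param cfg Scenario configuration.
#' @param d_mag_um Equivalent magnetic-sphere diameters (um).
#' @param dUx_mm_s Inlet speeds (mm/s).
#' @return data.frame with columns d_mag_um, dUx_mm_s, drift_mm, angle_deg.
#' @export
deflection_sweep <- function(cfg = load_config(),
                             d_mag_um = c(1.0, 1.2, 1.4, 1.6),
                             dUx_mm_s = c(0.2, 0.5)) {
  ob <- config_objects(cfg)
  station <- cfg$inference$station_x_mm * 1e-3
  fg <- field_grid(ob$magnet, ob$placement, ob$chamber,
                   spacing = ob$params$dx)
  rows <- list()
  for (du in dUx_mm_s) {
    fluid <- fluid_spec(ob$fluid$viscosity_eta, du * 1e-3)
    ref <- simulate_scenario(ob$chamber, NULL, ob$placement,
                             cell_model(ob$cell$cell_diameter, n_spions = 0,
                                        Ms = ob$cell$Ms, spion = ob$spion),
                             fluid, ob$params)$sol
    for (dm in d_mag_um) {
      cell <- cell_model(ob$cell$cell_diameter, d_mag = dm * 1e-6,
                         Ms = ob$cell$Ms, spion = ob$spion)
      sol <- simulate_scenario(ob$chamber, ob$magnet, ob$placement, cell,
                               fluid, ob$params, fg = fg)$sol
      dm_ <- deflection_metric(sol, ref, station)
      rows[[length(rows) + 1]] <- data.frame(
        d_mag_um = dm, dUx_mm_s = du, drift_mm = dm_$drift * 1e3,
        angle_deg = dm_$angle * 180 / pi)
    }
  }
  do.call(rbind, rows)
}

#' Magnet-repositioning study
#'
#' Re-runs the scenario for a set of magnet placements and reports the
#' near-wall accumulation centroid of each run plus the transmission
#' coefficient of every shifted placement relative to the first (base)
#' placement.
#'
#' @param cfg Scenario configuration (cell loading, fluid etc.).
#' @param placements List of \code{\link{magnet_placement}} objects; the
#'   first is the base.
#' @return data.frame with dist_x_mm, dist_y_mm, accumulation centroid
#'   (mm), and the transmission ratio vs the base placement (NA for the
#'   base row or when flagged).
#' @export
magnet_shift_study <- function(cfg = load_config(), placements) {
  stopifnot(length(placements) >= 2)
  ob <- config_objects(cfg)
  sols <- lapply(placements, function(pl) {
    fg <- field_grid(ob$magnet, pl, ob$chamber, spacing = ob$params$dx)
    simulate_scenario(ob$chamber, ob$magnet, pl, ob$cell, ob$fluid,
                      ob$params, fg = fg)$sol
  })
  fc <- lapply(placements, face_center, chamber_width = ob$chamber$width)
  rows <- lapply(seq_along(placements), function(i) {
    ac <- accumulation_centroid(sols[[i]])
    ratio <- NA_real_
    if (i > 1) {
      tc <- transmission_coefficient(sols[[1]], sols[[i]],
                                     fc[[i]] - fc[[1]])
      if (!tc$flagged) ratio <- tc$ratio
    }
    data.frame(dist_x_mm = placements[[i]]$dist_x * 1e3,
               dist_y_mm = placements[[i]]$dist_y * 1e3,
               accum_x_mm = if (is.null(ac)) NA_real_ else ac[1] * 1e3,
               accum_y_mm = if (is.null(ac)) NA_real_ else ac[2] * 1e3,
               transmission = ratio)
  })
  do.call(rbind, rows)
}
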