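# SPION loading <-> equivalent magnetic sphere, magnetic force, Stokes drag
# and the terminal (force-balance) cell velocity.

#' SPION geometry
#'
#' @param total_diameter Total particle diameter in metres (default 20 nm).
#' @param core_diameter Magnetic (magnetite) core diameter in metres
#'   (default 10 nm).
#' @return An object of class \code{spion_spec}.
#' @export
spion_spec <- function(total_diameter = 20e-9, core_diameter = 10e-9) {
  stopifnot(core_diameter > 0, core_diameter <= total_diameter)
  structure(list(total_diameter = total_diameter,
                 core_diameter = core_diameter),
            class = "spion_spec")
}

#' Magnetized cell model
#'
#' A cell of hydrodynamic diameter \code{cell_diameter} carrying all its
#' internalized magnetic material as a single equivalent sphere of diameter
#' \code{d_mag}. Exactly one of \code{d_mag} and \code{n_spions} must be
#' given; the other is filled in by core-volume equivalence.
#'
#' @param cell_diameter Hydrodynamic cell diameter (m, default 10 um).
#' @param d_mag Equivalent magnetic-sphere diameter (m).
#' @param n_spions SPION count per cell.
#' @param Ms Saturation magnetization of the core material (A/m, default
#'   4.8e5, bulk magnetite).
#' @param spion A \code{\link{spion_spec}}.
#' @return An object of class \code{cell_model} with both \code{d_mag} and
#'   \code{n_spions} populated.
#' @examples
#' cell_model(n_spions = 1e6)$d_mag   # 1.0 um
#' @export
cell_model <- function(cell_diameter = 10e-6, d_mag = NULL, n_spions = NULL,
                       Ms = 4.8e5, spion = spion_spec()) {
  stopifnot(cell_diameter > 0, Ms >= 0)
  if (is.null(d_mag) && is.null(n_spions))
    stop("give d_mag or n_spions")
  if (is.null(d_mag)) d_mag <- equivalent_magnetic_diameter(n_spions, spion)
  if (is.null(n_spions)) n_spions <- spions_from_diameter(d_mag, spion)
  stopifnot(d_mag >= 0)
  structure(list(cell_diameter = cell_diameter, d_mag = d_mag,
                 n_spions = n_spions, Ms = Ms, spion = spion),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "Magnetized cell: diameter %.3g um, d_mag %.3g um (%.3g SPIONs/cell), Ms %.3g A/m\n",
    x$cell_diameter * 1e6, x$d_mag * 1e6, x$n_spions, x$Ms))
  invisible(x)
}

#' Fluid properties and inlet plug-flow speed
#'
#' @param viscosity_eta Dynamic viscosity (Pa s, default 1.1e-3,
#'   physiological solution).
#' @param inlet_speed_dUx Uniform downstream fluid speed (m/s).
#' @return An object of class \code{fluid_spec}.
#' @export
fluid_spec <- function(viscosity_eta = 1.1e-3, inlet_speed_dUx = 0.2e-3) {
  stopifnot(viscosity_eta > 0, inlet_speed_dUx >= 0)
  structure(list(viscosity_eta = viscosity_eta,
                 inlet_speed_dUx = inlet_speed_dUx),
            class = "fluid_spec")
}

#' Equivalent magnetic-sphere diameter for a SPION count
#'
#' Conserves the total magnetic-core volume: \code{d_mag = core_diameter *
#' n^(1/3)}, so 1e6 internalized 10 nm cores are equivalent to a single
#' 1.0 um sphere.
#'
#' @param n_spions SPION count (>= 0, vectorized).
#' @param spion A \code{\link{spion_spec}}.
#' @return Diameter in metres.
#' @export
equivalent_magnetic_diameter <- function(n_spions, spion = spion_spec()) {
  if (any(n_spions < 0)) stop("n_spions must be >= 0")
  spion$core_diameter * n_spions^(1 / 3)
}

#' SPION count for an equivalent magnetic-sphere diameter
#'
#' Inverse of \code{\link{equivalent_magnetic_diameter}}.
#'
#' @param d_mag Equivalent sphere diameter (m, >= 0, vectorized).
#' @param spion A \code{\link{spion_spec}}.
#' @return SPION count (not rounded).
#' @export
spions_from_diameter <- function(d_mag, spion = spion_spec()) {
  if (any(d_mag < 0)) stop("d_mag must be >= 0")
  (d_mag / spion$core_diameter)^3
}

#' Saturated magnetic moment of the equivalent sphere
#'
#' \code{Ms * (pi/6) * d_mag^3} (A m^2). The SPIONs sit close to saturation
#' in the tesla-scale field of the magnet, so a field-independent saturated
#' moment is used.
#'
#' @param cell A \code{\link{cell_model}}.
#' @return Magnetic moment in A m^2.
#' @export
magnetic_moment <- function(cell) {
  cell$Ms * (pi / 6) * cell$d_mag^3
}

#' Magnetophoretic force on a saturated moment
#'
#' \code{F = m * grad|B|}, directed along the gradient of the field
#' magnitude (equivalently mu0 * m * grad|H| in a non-magnetic medium).
#'
#' @param moment Magnetic moment (A m^2).
#' @param grad_B_mag Gradient of |B| (T/m); vector or two-column matrix.
#' @return Force (N), same shape as \code{grad_B_mag}.
#' @export
magnetic_force <- function(moment, grad_B_mag) {
  moment * grad_B_mag
}

#' Terminal cell velocity from the force balance
#'
#' Solves \code{F_mag + F_drag = 0} with Stokes drag
#' \code{F_drag = -6 pi eta r_p (v_p - v_f)}, giving
#' \code{v_p = v_f + F_mag / (6 pi eta r_p)}; \code{r_p} is the hydrodynamic
#' cell radius, not the magnetic-sphere radius.
#'
#' @param cell A \code{\link{cell_model}}.
#' @param fluid A \code{\link{fluid_spec}}.
#' @param v_f Fluid velocity (m/s); vector or two-column matrix.
#' @param F_mag Magnetic force (N), same shape as \code{v_f}.
#' @return Particle velocity v_p, same shape as the inputs.
#' @export
terminal_velocity <- function(cell, fluid, v_f, F_mag) {
  r_p <- cell$cell_diameter / 2
  if (r_p <= 0 || fluid$viscosity_eta <= 0)
    stop("cell radius and viscosity must be positive")
  v_f + F_mag / (6 * pi * fluid$viscosity_eta * r_p)
}

#' Iron-oxide volume fraction of the cell
#'
#' \code{n * (core_diameter / cell_diameter)^3}: the fraction of the cell
#' volume occupied by magnetic-core material (< 1 percent across the tested
#' loading range).
#'
#' @param n_spions SPION count.
#' @param spion A \code{\link{spion_spec}}.
#' @param cell A \code{\link{cell_model}} (only the diameter is used).
#' @return Dimensionless volume fraction.
#' @export
iron_oxide_volume_fraction <- function(n_spions, spion = spion_spec(),
                                       cell = cell_model(n_spions = 0)) {
  if (cell$cell_diameter <= 0) stop("cell_diameter must be positive")
  n_spions * (spion$core_diameter / cell$cell_diameter)^3
}
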