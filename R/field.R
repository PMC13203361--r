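# Magnetostatics of an axially magnetized cylindrical permanent magnet,
# evaluated in the chamber mid-plane via the two-disk magnetic-charge model.
# The closed-form on-axis expression is kept as an independent oracle.

MU0 <- 4 * pi * 1e-7

#' Cylindrical permanent magnet specification
#'
#' @param diameter Magnet diameter in metres (default 10 mm).
#' @param height Magnet height (axial extent) in metres (default 10 mm).
#' @param remanence_Br Residual flux density Br in tesla (default 1.3 T,
#'   typical of a sintered NdFeB magnet).
#' @return An object of class \code{magnet_spec}.
#' @examples
#' m <- magnet_spec()
#' on_axis_Bz(m, 12e-3)
#' @export
magnet_spec <- function(diameter = 10e-3, height = 10e-3, remanence_Br = 1.3) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(height), height > 0,
            is.numeric(remanence_Br), remanence_Br >= 0)
  structure(list(diameter = diameter, height = height,
                 remanence_Br = remanence_Br),
            class = "magnet_spec")
}

#' @export
print.magnet_spec <- function(x, ...) {
  cat(sprintf("Cylindrical magnet: d = %.3g mm, h = %.3g mm, Br = %.3g T\n",
              x$diameter * 1e3, x$height * 1e3, x$remanence_Br))
  invisible(x)
}

#' Magnet pose relative to the chamber
#'
#' Chamber coordinates: origin at the inlet/left-bottom corner, x downstream,
#' y toward the magnet side. The magnet axis lies in the chamber mid-plane,
#' perpendicular to the flow by default, with its near face \code{dist_y}
#' outside the nearest chamber edge and its axis crossing the flow direction
#' at \code{dist_x} from the inlet.
#'
#' @param dist_x Distance of the magnet axis from the chamber inlet (m).
#' @param dist_y Distance of the near magnet face from the nearest chamber
#'   edge (m).
#' @param axis_direction Unit vector (chamber frame) pointing from the chamber
#'   toward the magnet; \code{c(0, 1)} (default) or \code{c(0, -1)}.
#' @return An object of class \code{magnet_placement}.
#' @export
magnet_placement <- function(dist_x = 25e-3, dist_y = 5e-3,
                             axis_direction = c(0, 1)) {
  stopifnot(dist_y >= 0, length(axis_direction) == 2)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("axis_direction must be a non-zero vector")
  axis_direction <- axis_direction / nrm
  if (!isTRUE(all.equal(abs(axis_direction), c(0, 1))))
    stop("axis_direction must be (0, 1) or (0, -1): the magnet axis is ",
         "perpendicular to the flow, in the mid-plane")
  structure(list(dist_x = dist_x, dist_y = dist_y,
                 axis_direction = axis_direction),
            class = "magnet_placement")
}

#' @export
print.magnet_placement <- function(x, ...) {
  cat(sprintf("Magnet placement: dist_x = %.3g mm, dist_y = %.3g mm, axis (%g, %g)\n",
              x$dist_x * 1e3, x$dist_y * 1e3,
              x$axis_direction[1], x$axis_direction[2]))
  invisible(x)
}

# Near-face centre in chamber coordinates; needs the chamber width when the
# magnet sits on the +y side.
face_center <- function(placement, chamber_width) {
  if (placement$axis_direction[2] > 0)
    c(placement$dist_x, chamber_width + placement$dist_y)
  else
    c(placement$dist_x, -placement$dist_y)
}

#' On-axis flux density of a cylindrical magnet (closed form)
#'
#' Axial component of B on the magnet axis at distance \code{z} from the near
#' face, outside the magnet:
#' \deqn{B_z(z) = \frac{B_r}{2}\left[\frac{z+L}{\sqrt{(z+L)^2+R^2}} -
#'   \frac{z}{\sqrt{z^2+R^2}}\right]}
#' with \eqn{L} the magnet height and \eqn{R} its radius. Serves as the
#' independent oracle for the numerical surface-charge evaluation in
#' \code{\link{field_at}}.
#'
#' @param magnet A \code{\link{magnet_spec}}.
#' @param z Distance(s) from the near face along the axis (m); must be >= 0.
#' @return Flux density in tesla (vectorized over \code{z}).
#' @export
on_axis_Bz <- function(magnet, z) {
  if (any(z < 0)) stop("z must be >= 0 (points inside the magnet unsupported)")
  R <- magnet$diameter / 2
  L <- magnet$height
  (magnet$remanence_Br / 2) *
    ((z + L) / sqrt((z + L)^2 + R^2) - z / sqrt(z^2 + R^2))
}

# Quadrature nodes over the two charged disks (+sigma near face, -sigma far
# face). Radial integral in u = rho^2 (Gauss-Legendre), azimuthal by midpoint
# over [0, pi] folded with weight 2 (mid-plane symmetry kills Bz).
disk_sources <- function(magnet, fc, axis, n_r, n_t) {
  R <- magnet$diameter / 2
  gl <- pracma::gaussLegendre(n_r, 0, R^2)
  th <- (seq_len(n_t) - 0.5) * pi / n_t
  e1 <- c(-axis[2], axis[1])                    # in-plane, perp to axis
  rho <- sqrt(gl$x)
  # outer products: n_r x n_t source lattice per disk
  sx <- sy <- sz <- w <- numeric(0)
  for (sgn in c(1, -1)) {
    s0 <- if (sgn > 0) 0 else magnet$height
    cx <- fc[1] + s0 * axis[1]
    cy <- fc[2] + s0 * axis[2]
    px <- outer(rho, cos(th))                   # in-plane offset along e1
    pz <- outer(rho, sin(th))                   # out-of-plane offset
    ww <- outer(gl$w / 2, rep(2 * pi / n_t, n_t)) * sgn
    sx <- c(sx, cx + e1[1] * px)
    sy <- c(sy, cy + e1[2] * px)
    sz <- c(sz, pz)
    w <- c(w, ww)
  }
  list(sx = sx, sy = sy, sz = sz, w = w)
}

# B (in-plane components, tesla) at mid-plane points px, py (vectors).
charge_model_B <- function(px, py, magnet, fc, axis, n_r = 32, n_t = 32) {
  src <- disk_sources(magnet, fc, axis, n_r, n_t)
  k <- magnet$remanence_Br / (4 * pi)
  Bx <- numeric(length(px))
  By <- numeric(length(px))
  for (s in seq_along(src$w)) {
    dx <- px - src$sx[s]
    dy <- py - src$sy[s]
    r2 <- dx * dx + dy * dy + src$sz[s]^2
    wi <- src$w[s] / (r2 * sqrt(r2))
    Bx <- Bx + wi * dx
    By <- By + wi * dy
  }
  list(Bx = k * Bx, By = k * By)
}

inside_magnet <- function(px, py, magnet, fc, axis) {
  s <- (px - fc[1]) * axis[1] + (py - fc[2]) * axis[2]
  rad <- abs((px - fc[1]) * (-axis[2]) + (py - fc[2]) * axis[1])
  s >= 0 & s <= magnet$height & rad <= magnet$diameter / 2
}

#' Magnetic field samples at chamber mid-plane points
#'
#' Evaluates the flux density of the magnet at arbitrary mid-plane points by
#' numerical quadrature of the two-disk magnetic-charge model, plus the field
#' magnitude, the equivalent H magnitude (|B|/mu0; the medium is water, whose
#' susceptibility is negligible) and the gradient of |B| by central finite
#' differences.
#'
#' @param magnet A \code{\link{magnet_spec}}.
#' @param placement A \code{\link{magnet_placement}}.
#' @param points Two-column matrix (or length-2 vector) of chamber-frame
#'   coordinates in metres.
#' @param chamber_width Chamber width in metres (locates the magnet;
#'   default 14 mm).
#' @param grad_step Finite-difference step for grad|B| (m); default 0.05 mm.
#' @param quad_n Quadrature order per disk dimension.
#' @return A data.frame with columns \code{x, y, Bx, By, Bmag, H_mag,
#'   gradBx, gradBy, gradBmag} (tesla, A/m, T/m).
#' @export
field_at <- function(magnet, placement, points, chamber_width = 14e-3,
                     grad_step = 0.05e-3, quad_n = 32) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  fc <- face_center(placement, chamber_width)
  axis <- placement$axis_direction
  if (any(inside_magnet(px, py, magnet, fc, axis)))
    stop("points inside the magnet body are unsupported")
  B <- charge_model_B(px, py, magnet, fc, axis, quad_n, quad_n)
  Bmag <- sqrt(B$Bx^2 + B$By^2)
  h <- grad_step
  bm <- function(dx, dy) {
    b <- charge_model_B(px + dx, py + dy, magnet, fc, axis, quad_n, quad_n)
    sqrt(b$Bx^2 + b$By^2)
  }
  gx <- (bm(h, 0) - bm(-h, 0)) / (2 * h)
  gy <- (bm(0, h) - bm(0, -h)) / (2 * h)
  data.frame(x = px, y = py, Bx = B$Bx, By = B$By, Bmag = Bmag,
             H_mag = Bmag / MU0, gradBx = gx, gradBy = gy,
             gradBmag = sqrt(gx^2 + gy^2))
}

#' Point-dipole field with the magnet's total moment (far-field oracle)
#'
#' @inheritParams field_at
#' @param points Two-column matrix of mid-plane points (m).
#' @return data.frame with \code{Bx, By, Bmag}.
#' @export
dipole_field <- function(magnet, placement, points, chamber_width = 14e-3) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  fc <- face_center(placement, chamber_width)
  axis <- placement$axis_direction
  ctr <- fc + axis * magnet$height / 2
  V <- pi * (magnet$diameter / 2)^2 * magnet$height
  m <- magnet$remanence_Br * V / MU0           # A m^2, along -axis (toward chamber,
  mvec <- -axis * m                            # sign immaterial for |B|)
  rx <- points[, 1] - ctr[1]; ry <- points[, 2] - ctr[2]
  r <- sqrt(rx^2 + ry^2)
  mdotr <- mvec[1] * rx + mvec[2] * ry
  k <- MU0 / (4 * pi)
  Bx <- k * (3 * mdotr * rx / r^5 - mvec[1] / r^3)
  By <- k * (3 * mdotr * ry / r^5 - mvec[2] / r^3)
  data.frame(Bx = Bx, By = By, Bmag = sqrt(Bx^2 + By^2))
}

#' Precompute field and |B|-gradient arrays on a transport grid
#'
#' @inheritParams field_at
#' @param chamber A \code{\link{chamber_spec}}.
#' @param spacing Grid spacing (m); cell-centred nodes.
#' @param grad_step Finite-difference step; default \code{min(0.1 mm,
#'   spacing/2)}.
#' @return An object of class \code{field_grid}: node coordinate vectors
#'   \code{x}, \code{y} and matrices (nx x ny) \code{Bx, By, Bmag, gradBx,
#'   gradBy, gradBmag}.
#' @export
field_grid <- function(magnet, placement, chamber, spacing = 1e-4,
                       grad_step = NULL, quad_n = 32) {
  if (is.null(grad_step)) grad_step <- min(0.1e-3, spacing / 2)
  g <- chamber_grid(chamber, spacing)
  fc <- face_center(placement, chamber$width)
  axis <- placement$axis_direction
  pts <- cbind(rep(g$x, times = g$ny), rep(g$y, each = g$nx))
  if (any(inside_magnet(pts[, 1], pts[, 2], magnet, fc, axis)))
    stop("grid overlaps the magnet body")
  shp <- function(v) matrix(v, g$nx, g$ny)
  B <- charge_model_B(pts[, 1], pts[, 2], magnet, fc, axis, quad_n, quad_n)
  bmag_at <- function(dx, dy) {
    b <- charge_model_B(pts[, 1] + dx, pts[, 2] + dy, magnet, fc, axis,
                        quad_n, quad_n)
    sqrt(b$Bx^2 + b$By^2)
  }
  h <- grad_step
  gx <- (bmag_at(h, 0) - bmag_at(-h, 0)) / (2 * h)
  gy <- (bmag_at(0, h) - bmag_at(0, -h)) / (2 * h)
  structure(list(x = g$x, y = g$y, spacing = spacing,
                 Bx = shp(B$Bx), By = shp(B$By),
                 Bmag = shp(sqrt(B$Bx^2 + B$By^2)),
                 gradBx = shp(gx), gradBy = shp(gy),
                 gradBmag = shp(sqrt(gx^2 + gy^2)),
                 magnet = magnet, placement = placement),
            class = "field_grid")
}

#' Export a field grid as a CSV table
#'
#' Columns \code{x_mm, y_mm, Bx, By, Bmag, gradBmag}.
#' @param fg A \code{\link{field_grid}}.
#' @param path Output CSV path.
#' @export
write_field_csv <- function(fg, path) {
  df <- data.frame(x_mm = rep(fg$x, times = length(fg$y)) * 1e3,
                   y_mm = rep(fg$y, each = length(fg$x)) * 1e3,
                   Bx = as.vector(fg$Bx), By = as.vector(fg$By),
                   Bmag = as.vector(fg$Bmag),
                   gradBmag = as.vector(fg$gradBmag))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a quick PNG preview of |B| over the chamber
#'
#' @param fg A \code{\link{field_grid}}.
#' @param path Output PNG path.
#' @export
plot_field_preview <- function(fg, path) {
  grDevices::png(path, width = 800, height = 400)
  on.exit(grDevices::dev.off())
  graphics::image(fg$x * 1e3, fg$y * 1e3, fg$Bmag,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", main = "|B| (T)")
  invisible(path)
}
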