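# Synthetic fluorescence recordings: render concentration fields (or sparse
# cell trajectories) into camera frames with Poisson/Gaussian noise and
# ground-truth masks. Stands in for the unavailable experimental videos.

#' Camera / acquisition model
#'
#' Defaults emulate the recordings: a fixed 22.5 x 12 mm^2 field of view at
#' 50 px/mm, 16-bit, 50 fps capability with frames analysed on a 30 s
#' cadence over the 0-3 min transient.
#'
#' @param pixel_size Pixel pitch (m/px, default 0.02 mm).
#' @param fov Field-of-view extent c(x, y) in metres (default 22.5 x 12 mm).
#' @param fov_origin Lower-left corner of the FOV in chamber coordinates (m);
#'   default places the FOV flush against the magnet-side wall of the
#'   default chamber, the region of most pronounced magnetic displacement.
#' @param bit_depth Bits per pixel (default 16).
#' @param background Background offset (counts).
#' @param gain Counts per unit concentration (mol/m^3).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param shot_noise Apply Poisson shot noise before read noise?
#' @param fps Acquisition frame rate (1/s), metadata.
#' @return An object of class \code{camera_model}.
#' @export
camera_model <- function(pixel_size = 0.02e-3, fov = c(22.5e-3, 12e-3),
                         fov_origin = c(4.75e-3, 2e-3), bit_depth = 16,
                         background = 200, gain = 1500,
                         read_noise_sd = 50, shot_noise = TRUE, fps = 50) {
  stopifnot(pixel_size > 0, all(fov > 0), bit_depth %in% c(8, 16),
            background >= 0, gain >= 0, read_noise_sd >= 0)
  npx <- round(fov[1] / pixel_size)
  npy <- round(fov[2] / pixel_size)
  structure(list(pixel_size = pixel_size, fov = fov, fov_origin = fov_origin,
                 npx = npx, npy = npy, bit_depth = bit_depth,
                 background = background, gain = gain,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 fps = fps),
            class = "camera_model")
}

# Pixel-centre coordinates in chamber frame. Frames are stored as
# npy x npx matrices: row = y (row 1 = smallest y), column = x.
camera_pixel_centers <- function(camera) {
  list(x = camera$fov_origin[1] + (seq_len(camera$npx) - 0.5) * camera$pixel_size,
       y = camera$fov_origin[2] + (seq_len(camera$npy) - 0.5) * camera$pixel_size)
}

check_fov_inside <- function(camera, chamber) {
  o <- camera$fov_origin
  if (o[1] < 0 || o[2] < 0 || o[1] + camera$fov[1] > chamber$length ||
      o[2] + camera$fov[2] > chamber$width)
    stop("camera field of view extends outside the chamber")
  invisible(TRUE)
}

# Resample a node field (nx x ny, chamber grid) onto camera pixels.
resample_to_pixels <- function(sol_x, sol_y, cfield, camera) {
  pc <- camera_pixel_centers(camera)
  px <- rep(pc$x, each = camera$npy)
  py <- rep(pc$y, times = camera$npx)
  matrix(interp_grid(sol_x, sol_y, cfield, px, py), camera$npy, camera$npx)
}

#' Render a concentration time series into a synthetic fluorescence stack
#'
#' Per frame: the concentration field is bilinearly resampled to the pixel
#' grid, scaled to \code{background + gain * c}, degraded with Poisson shot
#' noise then Gaussian read noise, and clipped to the bit depth. The
#' ground-truth mask marks pixels whose noiseless signal exceeds 10 percent
#' of the gain; it is independent of the noise realization.
#'
#' @param sol A \code{\link{transport_solution}} with snapshots.
#' @param camera A \code{\link{camera_model}}.
#' @param seed Integer seed controlling the noise (reproducible stacks).
#' @return An object of class \code{frame_stack}: lists \code{frames} and
#'   \code{masks} (npy x npx matrices), \code{timestamps} (s), \code{camera},
#'   \code{seed}.
#' @export
render_frames <- function(sol, camera, seed = 1L) {
  check_fov_inside(camera, sol$chamber)
  maxval <- 2^camera$bit_depth - 1
  frames <- masks <- vector("list", length(sol$conc))
  set.seed(seed)
  for (k in seq_along(sol$conc)) {
    cpix <- resample_to_pixels(sol$x, sol$y, sol$conc[[k]], camera)
    signal <- camera$gain * cpix
    clean <- camera$background + signal
    noisy <- clean
    if (camera$shot_noise)
      noisy <- matrix(stats::rpois(length(clean), pmax(clean, 0)),
                      nrow(clean), ncol(clean))
    if (camera$read_noise_sd > 0)
      noisy <- noisy + stats::rnorm(length(noisy), 0, camera$read_noise_sd)
    frames[[k]] <- pmin(pmax(round(noisy), 0), maxval)
    masks[[k]] <- signal > 0.1 * camera$gain
  }
  structure(list(frames = frames, masks = masks, timestamps = sol$times,
                 camera = camera, seed = seed),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %d x %d px, t = %.3g..%.3g s, seed %d\n",
              length(x$frames), x$camera$npy, x$camera$npx,
              min(x$timestamps), max(x$timestamps), x$seed))
  invisible(x)
}

#' Render sparse single cells from trajectories
#'
#' Emulates the low-concentration regime: each cell is a 2-D Gaussian spot
#' at its trajectory position interpolated to the frame timestamp; the
#' ground-truth mask is the union of per-cell discs of radius
#' \code{2 * sigma}.
#'
#' @param trajectories List of \code{\link{trace_trajectory}} results.
#' @param camera A \code{\link{camera_model}}.
#' @param timestamps Frame times (s).
#' @param amplitude Peak spot intensity above background (counts).
#' @param sigma Gaussian spot radius (m, default 50 um).
#' @param seed Noise seed.
#' @return A \code{frame_stack}.
#' @export
render_sparse_cells <- function(trajectories, camera, timestamps,
                                amplitude = 5000, sigma = 50e-6, seed = 1L) {
  stopifnot(length(trajectories) >= 1)
  pc <- camera_pixel_centers(camera)
  maxval <- 2^camera$bit_depth - 1
  frames <- masks <- vector("list", length(timestamps))
  set.seed(seed)
  for (k in seq_along(timestamps)) {
    tk <- timestamps[k]
    signal <- matrix(0, camera$npy, camera$npx)
    mask <- matrix(FALSE, camera$npy, camera$npx)
    for (tr in trajectories) {
      if (tk < min(tr$times) || tk > max(tr$times)) next
      cx <- stats::approx(tr$times, tr$positions[, 1], tk)$y
      cy <- stats::approx(tr$times, tr$positions[, 2], tk)$y
      gx <- exp(-(pc$x - cx)^2 / (2 * sigma^2))
      gy <- exp(-(pc$y - cy)^2 / (2 * sigma^2))
      signal <- signal + amplitude * outer(gy, gx)
      dx2 <- outer(rep(1, camera$npy), (pc$x - cx)^2)
      dy2 <- outer((pc$y - cy)^2, rep(1, camera$npx))
      mask <- mask | (dx2 + dy2 <= (2 * sigma)^2)
    }
    clean <- camera$background + signal
    noisy <- clean
    if (camera$shot_noise)
      noisy <- matrix(stats::rpois(length(clean), pmax(clean, 0)),
                      nrow(clean), ncol(clean))
    if (camera$read_noise_sd > 0)
      noisy <- noisy + stats::rnorm(length(noisy), 0, camera$read_noise_sd)
    frames[[k]] <- pmin(pmax(round(noisy), 0), maxval)
    masks[[k]] <- mask
  }
  structure(list(frames = frames, masks = masks, timestamps = timestamps,
                 camera = camera, seed = seed),
            class = "frame_stack")
}

#' Write a frame stack to disk (multi-page TIFF + JSON sidecar)
#'
#' Frames and ground-truth masks go to 16-bit multi-page TIFFs; timestamps,
#' camera parameters and the seed go to a JSON sidecar.
#'
#' @param stack A \code{frame_stack}.
#' @param prefix Path prefix; writes \code{<prefix>.tif},
#'   \code{<prefix>_masks.tif}, \code{<prefix>.json}.
#' @export
write_frame_stack <- function(stack, prefix) {
  maxval <- 2^stack$camera$bit_depth - 1
  tiff::writeTIFF(lapply(stack$frames, function(f) f / maxval),
                  paste0(prefix, ".tif"), bits.per.sample = 16L)
  tiff::writeTIFF(lapply(stack$masks, function(m) m * 1.0),
                  paste0(prefix, "_masks.tif"), bits.per.sample = 16L)
  side <- list(timestamps = stack$timestamps, seed = stack$seed,
               camera = unclass(stack$camera))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a frame stack written by \code{\link{write_frame_stack}}
#' @param prefix Path prefix used when writing.
#' @return A \code{frame_stack}.
#' @export
read_frame_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cam <- do.call(camera_model, side$camera[names(side$camera) %in%
                                             names(formals(camera_model))])
  maxval <- 2^cam$bit_depth - 1
  frames <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  frames <- lapply(frames, function(f) round(f * maxval))
  masks <- tiff::readTIFF(paste0(prefix, "_masks.tif"), all = TRUE)
  masks <- lapply(masks, function(m) m > 0.5)
  structure(list(frames = frames, masks = masks,
                 timestamps = side$timestamps, camera = cam,
                 seed = side$seed),
            class = "frame_stack")
}
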