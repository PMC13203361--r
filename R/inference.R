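# Deflection-vs-loading calibration from forward simulations, inversion of
# measured deflections to SPIONs/cell, reliability gating and the
# approximation-error bookkeeping.

#' Build the deflection-vs-loading calibration curve
#'
#' Runs the transport model for each loading on the configured scenario,
#' records the lateral drift at the magnet-axis station against the
#' no-magnet reference, and fits a monotone piecewise-cubic interpolant in
#' log10(loading). The magnet field grid is computed once and shared.
#'
#' @param cfg A \code{\link{load_config}} scenario configuration.
#' @param loadings SPIONs/cell grid (>= 4 ascending values, default
#'   \code{cfg$inference$calibration_loadings}, which extends one decade
#'   below the studied loadings so that low-loading inversions are not
#'   pinned to the grid floor).
#' @return An object of class \code{calibration_curve}: \code{loadings},
#'   \code{drifts_mm}, interpolant, station, validity range and the scenario
#'   hash.
#' @export
build_calibration <- function(cfg = load_config(), loadings = NULL) {
  if (is.null(loadings)) loadings <- cfg$inference$calibration_loadings
  if (is.null(loadings)) loadings <- cfg$inference$loadings
  loadings <- sort(as.numeric(loadings))
  if (length(loadings) < 4) stop("need >= 4 calibration loadings")
  ob <- config_objects(cfg)
  station <- cfg$inference$station_x_mm * 1e-3
  fg <- field_grid(ob$magnet, ob$placement, ob$chamber,
                   spacing = ob$params$dx)
  ref <- simulate_scenario(ob$chamber, NULL, ob$placement,
                           cell_model(ob$cell$cell_diameter, n_spions = 0,
                                      Ms = ob$cell$Ms, spion = ob$spion),
                           ob$fluid, ob$params)$sol
  drifts <- vapply(loadings, function(L) {
    cell <- cell_model(ob$cell$cell_diameter, n_spions = L, Ms = ob$cell$Ms,
                       spion = ob$spion)
    sol <- simulate_scenario(ob$chamber, ob$magnet, ob$placement, cell,
                             ob$fluid, ob$params, fg = fg)$sol
    deflection_metric(sol, ref, station)$drift * 1e3
  }, numeric(1))
  if (any(diff(drifts) <= 0))
    stop("simulated deflections are not strictly increasing in loading; ",
         "the scenario is broken (drifts: ",
         paste(signif(drifts, 4), collapse = ", "), " mm)")
  fun <- stats::splinefun(log10(loadings), drifts, method = "hyman")
  structure(list(loadings = loadings, drifts_mm = drifts, fun = fun,
                 station_x_mm = cfg$inference$station_x_mm,
                 range = range(loadings), scenario_hash = config_hash(cfg)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Deflection-vs-loading calibration curve\n")
  cat(sprintf("  station x = %g mm, scenario %s\n", x$station_x_mm,
              substr(x$scenario_hash, 1, 8)))
  print(data.frame(loading = x$loadings, drift_mm = signif(x$drifts_mm, 4)))
  invisible(x)
}

#' Predict drift (mm) for a loading on the calibration curve
#' @param object A \code{calibration_curve}.
#' @param loading SPIONs/cell (vectorized); must lie within the curve range.
#' @param ... Unused.
#' @export
predict.calibration_curve <- function(object, loading, ...) {
  if (any(loading < object$range[1] | loading > object$range[2]))
    warning("loading outside the calibration range; extrapolating")
  object$fun(log10(loading))
}

#' @export
plot.calibration_curve <- function(x, ...) {
  lg <- seq(log10(x$range[1]), log10(x$range[2]), length.out = 200)
  graphics::plot(10^lg, x$fun(lg), type = "l", log = "x",
                 xlab = "SPIONs/cell", ylab = "lateral drift (mm)",
                 main = "Deflection-vs-loading calibration", ...)
  graphics::points(x$loadings, x$drifts_mm, pch = 19)
  invisible(x)
}

#' Store / load a calibration curve as JSON
#' @param curve A \code{calibration_curve}.
#' @param path JSON path.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(list(loadings = curve$loadings,
                            drifts_mm = curve$drifts_mm,
                            station_x_mm = curve$station_x_mm,
                            scenario_hash = curve$scenario_hash),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(loadings = j$loadings, drifts_mm = j$drifts_mm,
                 fun = stats::splinefun(log10(j$loadings), j$drifts_mm,
                                        method = "hyman"),
                 station_x_mm = j$station_x_mm, range = range(j$loadings),
                 scenario_hash = j$scenario_hash),
            class = "calibration_curve")
}

#' Estimate SPION loading from a measured lateral drift
#'
#' Inverts the calibration curve in log10(loading). Drifts below the curve
#' minimum return the range floor flagged not reliable (the detection-limit
#' regime, where estimates become non-applicable); drifts above the maximum
#' return the range ceiling, flagged. Estimates under the reliability
#' threshold (default 1e5 SPIONs/cell) are never flagged reliable.
#'
#' @param drift_mm Measured lateral drift (mm, signed toward the magnet).
#' @param curve A \code{\link{build_calibration}} result.
#' @param reliability_threshold Loading below which estimates are
#'   unreliable.
#' @param method \code{"calibration-inversion"} (root of the interpolant) or
#'   \code{"forward-fit"} (minimizes |drift(L) - drift_mm| over the range,
#'   optionally with a user forward model \code{drift_fun(loading) -> mm}).
#' @param drift_fun Forward model for \code{method = "forward-fit"};
#'   defaults to the calibration interpolant.
#' @return An object of class \code{estimate_result}: estimated loading,
#'   flags (\code{reliable}, \code{extrapolated}), method.
#' @export
estimate_loading <- function(drift_mm, curve, reliability_threshold = 1e5,
                             method = c("calibration-inversion",
                                        "forward-fit"),
                             drift_fun = NULL) {
  method <- match.arg(method)
  lo <- log10(curve$range[1]); hi <- log10(curve$range[2])
  extrapolated <- "none"
  if (method == "calibration-inversion") {
    if (drift_mm <= curve$drifts_mm[1]) {
      est <- curve$range[1]; extrapolated <- "below-range"
    } else if (drift_mm >= curve$drifts_mm[length(curve$drifts_mm)]) {
      est <- curve$range[2]; extrapolated <- "above-range"
    } else {
      r <- stats::uniroot(function(l) curve$fun(l) - drift_mm, c(lo, hi),
                          tol = 1e-12)
      est <- 10^r$root
    }
  } else {
    f <- if (is.null(drift_fun)) function(L) curve$fun(log10(L))
         else drift_fun
    opt <- stats::optimize(function(l) abs(f(10^l) - drift_mm), c(lo, hi),
                           tol = 1e-10)
    est <- 10^opt$minimum
    if (abs(opt$minimum - lo) < 1e-6) extrapolated <- "below-range"
    if (abs(opt$minimum - hi) < 1e-6) extrapolated <- "above-range"
  }
  reliable <- extrapolated != "below-range" && est >= reliability_threshold
  structure(list(estimated_loading = est, drift_mm = drift_mm,
                 reliable = reliable, extrapolated = extrapolated,
                 method = method),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("Estimated loading: %.3g SPIONs/cell (%s)%s\n",
              x$estimated_loading, x$method,
              if (x$reliable) "" else "  [not reliable]"))
  if (x$extrapolated != "none")
    cat("  measured drift ", x$extrapolated, " of the calibration curve\n")
  invisible(x)
}

#' Approximation error of an estimate against the nominal loading
#'
#' \code{(estimated - nominal) / nominal * 100}; the magnitude is reported
#' (magnitudes are the conventional presentation) and the signed value
#' retained.
#'
#' @param estimated Estimated SPIONs/cell.
#' @param nominal Nominal SPIONs/cell (> 0).
#' @return List with \code{error_pct} (magnitude) and \code{signed_pct}.
#' @export
approximation_error <- function(estimated, nominal) {
  if (any(nominal <= 0)) stop("nominal loading must be > 0")
  signed <- (estimated - nominal) / nominal * 100
  list(error_pct = abs(signed), signed_pct = signed)
}

#' Measure the lateral drift from a rendered frame stack
#'
#' The pixel-space twin of \code{\link{deflection_metric}}: descriptors are
#' extracted inside a narrow region of interest centred on the station
#' (magnet-axis) column, and the drift is the mean centroid-y of the valid
#' late frames minus the reference centroid from the no-field stack,
#' measured identically.
#'
#' @param stack Frame stack of the magnet-on run.
#' @param ref_stack Frame stack of the no-field reference run (same camera).
#' @param station_x_mm Station (mm, chamber frame).
#' @param half_width_mm ROI half width around the station (mm).
#' @param late_frac Fraction of the time span (from the end) averaged over.
#' @param backend Segmentation backend.
#' @param weighting Centroid weighting (see
#'   \code{\link{extract_descriptors}}).
#' @param min_area_mm2,max_jump_mm QC thresholds; the effective area floor
#'   is \code{max(min_area_mm2, min_area_px)} so that noise speckle (whose
#'   connected-component size is a pixel-count, not a physical-area,
#'   phenomenon) is rejected at any camera resolution.
#' @param min_area_px Minimum component size in pixels.
#' @return List with \code{drift_mm}, \code{centroid_y_mm},
#'   \code{reference_y_mm}, \code{n_frames}.
#' @export
measure_drift <- function(stack, ref_stack, station_x_mm,
                          half_width_mm = 0.5, late_frac = 0.25,
                          backend = default_backend(),
                          weighting = "intensity", min_area_mm2 = 0.02,
                          min_area_px = 50, max_jump_mm = 2) {
  cam <- stack$camera
  px_mm <- cam$pixel_size * 1e3
  x0_mm <- cam$fov_origin[1] * 1e3
  c1 <- max(1L, floor((station_x_mm - half_width_mm - x0_mm) / px_mm) + 1L)
  c2 <- min(cam$npx, ceiling((station_x_mm + half_width_mm - x0_mm) / px_mm))
  if (c2 < c1) stop("station lies outside the camera field of view")
  roi <- list(rows = c(1L, cam$npy), cols = c(c1, c2))
  area_floor <- max(min_area_mm2, min_area_px * px_mm^2)
  late_y <- function(st) {
    d <- extract_descriptors(st, backend = backend, reference_y = 0,
                             roi = roi, weighting = weighting)
    d <- qc_filter(d, min_area_mm2 = area_floor,
                   max_jump_mm = max_jump_mm)$accepted
    if (nrow(d) == 0) return(list(y = NA_real_, n = 0L))
    tcut <- max(st$timestamps) - late_frac * diff(range(st$timestamps))
    dl <- d[d$time >= tcut, , drop = FALSE]
    if (nrow(dl) == 0) dl <- d[nrow(d), , drop = FALSE]
    list(y = mean(dl$cy_mm), n = nrow(dl))
  }
  a <- late_y(stack)
  b <- late_y(ref_stack)
  list(drift_mm = a$y - b$y, centroid_y_mm = a$y, reference_y_mm = b$y,
       n_frames = a$n)
}

#' Parameter-recovery study over the loading grid
#'
#' For each nominal loading and seed: simulate the plume, render noisy
#' frames, render the no-field reference with the same camera, measure the
#' drift at the station, invert it on the calibration curve and record the
#' approximation error. The machine twin of a nominal-vs-estimated loading
#' table.
#'
#' @param cfg Scenario configuration.
#' @param loadings Nominal loadings (default the studied grid
#'   \code{cfg$inference$loadings}).
#' @param n_seeds Noise realizations per loading.
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @param curve Optional precomputed \code{\link{build_calibration}} curve.
#' @param noise_scale Multiplier on the camera read-noise sd (degradation
#'   studies).
#' @return An object of class \code{recovery_study}: data.frame with columns
#'   nominal, seed, drift_mm, estimated, error_pct, signed_pct, reliable.
#' @export
recovery_study <- function(cfg = load_config(), loadings = NULL,
                           n_seeds = 5, seed = 1, curve = NULL,
                           noise_scale = 1) {
  if (is.null(curve)) curve <- build_calibration(cfg)
  if (is.null(loadings)) loadings <- cfg$inference$loadings
  ob <- config_objects(cfg)
  cam <- ob$camera
  cam$read_noise_sd <- cam$read_noise_sd * noise_scale
  snaps <- ob$params$t_end * c(0.7, 0.8, 0.9, 1)
  fg <- field_grid(ob$magnet, ob$placement, ob$chamber,
                   spacing = ob$params$dx)
  ref_sol <- simulate_scenario(ob$chamber, NULL, ob$placement,
                               cell_model(ob$cell$cell_diameter,
                                          n_spions = 0, Ms = ob$cell$Ms,
                                          spion = ob$spion),
                               ob$fluid, ob$params,
                               snapshot_times = snaps)$sol
  sols <- lapply(loadings, function(L) {
    cell <- cell_model(ob$cell$cell_diameter, n_spions = L, Ms = ob$cell$Ms,
                       spion = ob$spion)
    simulate_scenario(ob$chamber, ob$magnet, ob$placement, cell, ob$fluid,
                      ob$params, fg = fg, snapshot_times = snaps)$sol
  })
  rows <- list()
  for (i in seq_len(n_seeds)) {
    sub <- (seed * 7919 + i * 104729) %% 2147483647
    ref_stack <- render_frames(ref_sol, cam, seed = sub)
    for (j in seq_along(loadings)) {
      stack <- render_frames(sols[[j]], cam, seed = (sub + j) %% 2147483647)
      md <- measure_drift(stack, ref_stack, curve$station_x_mm,
                          weighting = cfg$descriptors$weighting)
      est <- estimate_loading(md$drift_mm, curve,
                              cfg$inference$reliability_threshold)
      err <- approximation_error(est$estimated_loading, loadings[j])
      rows[[length(rows) + 1]] <- data.frame(
        nominal = loadings[j], seed = i, drift_mm = md$drift_mm,
        estimated = est$estimated_loading, error_pct = err$error_pct,
        signed_pct = err$signed_pct, reliable = est$reliable)
    }
  }
  structure(do.call(rbind, rows), class = c("recovery_study", "data.frame"))
}

#' Summarize a recovery study per nominal loading
#' @param study A \code{\link{recovery_study}} result.
#' @return data.frame with mean/sd of the error magnitude and the reliable
#'   fraction per nominal loading.
#' @export
summarize_recovery <- function(study) {
  d <- as.data.frame(study)
  out <- do.call(rbind, lapply(split(d, d$nominal), function(s) {
    data.frame(nominal = s$nominal[1], n = nrow(s),
               mean_estimated = mean(s$estimated),
               mean_error_pct = mean(s$error_pct),
               sd_error_pct = stats::sd(s$error_pct),
               reliable_frac = mean(s$reliable))
  }))
  out[order(out$nominal, decreasing = TRUE), ]
}
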