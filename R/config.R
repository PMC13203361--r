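# Scenario configuration: YAML in and out (lengths in mm there), SI units
# internally, strict validation, canonical hashing for run manifests.

default_config_list <- function() {
  list(
    chamber = list(length_mm = 32, width_mm = 14, height_um = 175,
                   inlet_band_mm = c(6, 8)),
    magnet = list(diameter_mm = 10, height_mm = 10, remanence_T = 1.3),
    placement = list(dist_x_mm = 25, dist_y_mm = 5, axis = c(0, 1)),
    spion = list(total_diameter_nm = 20, core_diameter_nm = 10),
    cell = list(diameter_um = 10, n_spions = 1e6, Ms_A_per_m = 4.8e5),
    fluid = list(viscosity_mPa_s = 1.1, dUx_mm_s = 0.2),
    transport = list(D_m2_s = 1e-10, dx_mm = 0.1, t_end_s = 180,
                     cfl = 0.5, inlet_conc = 1),
    camera = list(pixel_size_mm = 0.02, fov_mm = c(22.5, 12),
                  fov_origin_mm = c(4.75, 2), bit_depth = 16,
                  background = 200, gain = 1500, read_noise_sd = 50,
                  shot_noise = TRUE, fps = 50),
    descriptors = list(min_area_mm2 = 0.5, max_jump_mm = 2,
                       reference_frames = 3, weighting = "intensity"),
    inference = list(loadings = c(1e5, 5e5, 1e6, 5e6),
                     calibration_loadings = c(1e4, 1e5, 5e5, 1e6, 5e6),
                     station_x_mm = 25, reliability_threshold = 1e5),
    seed = 1
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", paste0(path, key), " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    } else {
      val <- user[[key]]
      # YAML sequences of mixed int/double arrive as lists; flatten scalars
      if (is.list(val) && is.atomic(defaults[[key]]) &&
          all(vapply(val, function(v) is.atomic(v) && length(v) == 1,
                     logical(1))))
        val <- unlist(val)
      defaults[[key]] <- val
    }
  }
  defaults
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$chamber$length_mm > 0, "chamber.length_mm must be > 0")
  chk(cfg$chamber$width_mm > 0, "chamber.width_mm must be > 0")
  chk(cfg$chamber$height_um > 0, "chamber.height_um must be > 0")
  b <- cfg$chamber$inlet_band_mm
  chk(length(b) == 2 && b[1] >= 0 && b[2] <= cfg$chamber$width_mm &&
        b[1] < b[2], "chamber.inlet_band_mm must be inside [0, width]")
  chk(cfg$magnet$diameter_mm > 0, "magnet.diameter_mm must be > 0")
  chk(cfg$magnet$height_mm > 0, "magnet.height_mm must be > 0")
  chk(cfg$magnet$remanence_T >= 0, "magnet.remanence_T must be >= 0")
  chk(cfg$placement$dist_x_mm >= 0 &&
        cfg$placement$dist_x_mm <= cfg$chamber$length_mm,
      "placement.dist_x_mm must lie within the chamber length")
  chk(cfg$placement$dist_y_mm >= 0, "placement.dist_y_mm must be >= 0")
  chk(cfg$spion$core_diameter_nm > 0 &&
        cfg$spion$core_diameter_nm <= cfg$spion$total_diameter_nm,
      "spion core diameter must be in (0, total diameter]")
  chk(cfg$cell$diameter_um > 0, "cell.diameter_um must be > 0")
  chk(cfg$cell$n_spions >= 0, "cell.n_spions must be >= 0")
  chk(cfg$fluid$viscosity_mPa_s > 0, "fluid.viscosity_mPa_s must be > 0")
  chk(cfg$fluid$dUx_mm_s >= 0, "fluid.dUx_mm_s must be >= 0")
  chk(cfg$transport$D_m2_s >= 0, "transport.D_m2_s must be >= 0")
  chk(cfg$transport$dx_mm > 0, "transport.dx_mm must be > 0")
  chk(cfg$transport$t_end_s > 0, "transport.t_end_s must be > 0")
  chk(cfg$camera$pixel_size_mm > 0, "camera.pixel_size_mm must be > 0")
  chk(cfg$inference$reliability_threshold > 0,
      "inference.reliability_threshold must be > 0")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  cfg
}

#' Load a scenario configuration from YAML
#'
#' Missing keys are filled from the defaults (the printed experimental
#' setup: 32 x 14 mm chamber, 10 x 10 mm 1.3 T magnet 5 mm from the edge and
#' 25 mm from the inlet, 10 um cells in 1.1 mPa s solution). Unknown keys
#' are rejected; all violations are reported together. Lengths are mm (or
#' the unit in the key name) in YAML, SI internally.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A validated configuration list of class \code{scenario_config}.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- validate_config(merge_config(default_config_list(), user))
  structure(cfg, class = "scenario_config")
}

#' Save a scenario configuration as YAML
#' @param cfg A \code{scenario_config}.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration:\n")
  cat(sprintf("  chamber %g x %g mm, magnet %g mm / %g T at (x = %g, dist_y = %g) mm\n",
              x$chamber$length_mm, x$chamber$width_mm, x$magnet$diameter_mm,
              x$magnet$remanence_T, x$placement$dist_x_mm,
              x$placement$dist_y_mm))
  cat(sprintf("  cell %g um, %.3g SPIONs/cell; dUx = %g mm/s; dx = %g mm, t_end = %g s\n",
              x$cell$diameter_um, x$cell$n_spions, x$fluid$dUx_mm_s,
              x$transport$dx_mm, x$transport$t_end_s))
  invisible(x)
}

# Internal: turn the config into the SI-unit model objects.
config_objects <- function(cfg) {
  spion <- spion_spec(cfg$spion$total_diameter_nm * 1e-9,
                      cfg$spion$core_diameter_nm * 1e-9)
  list(
    chamber = chamber_spec(cfg$chamber$length_mm * 1e-3,
                           cfg$chamber$width_mm * 1e-3,
                           cfg$chamber$height_um * 1e-6,
                           cfg$chamber$inlet_band_mm * 1e-3),
    magnet = magnet_spec(cfg$magnet$diameter_mm * 1e-3,
                         cfg$magnet$height_mm * 1e-3,
                         cfg$magnet$remanence_T),
    placement = magnet_placement(cfg$placement$dist_x_mm * 1e-3,
                                 cfg$placement$dist_y_mm * 1e-3,
                                 cfg$placement$axis),
    spion = spion,
    cell = cell_model(cfg$cell$diameter_um * 1e-6,
                      n_spions = cfg$cell$n_spions,
                      Ms = cfg$cell$Ms_A_per_m, spion = spion),
    fluid = fluid_spec(cfg$fluid$viscosity_mPa_s * 1e-3,
                       cfg$fluid$dUx_mm_s * 1e-3),
    params = transport_params(cfg$transport$D_m2_s,
                              cfg$transport$dx_mm * 1e-3, NULL,
                              cfg$transport$t_end_s, cfg$transport$cfl,
                              cfg$transport$inlet_conc),
    camera = camera_model(cfg$camera$pixel_size_mm * 1e-3,
                          cfg$camera$fov_mm * 1e-3,
                          cfg$camera$fov_origin_mm * 1e-3,
                          cfg$camera$bit_depth, cfg$camera$background,
                          cfg$camera$gain, cfg$camera$read_noise_sd,
                          cfg$camera$shot_noise, cfg$camera$fps)
  )
}

#' Canonical hash of a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON encoding, so the hash
#' is stable under key reordering.
#'
#' @param cfg A \code{scenario_config} (or any list).
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)))
      x <- lapply(x[order(names(x))], sort_rec)
    x
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(sort_rec(unclass(cfg)), tf, auto_unbox = TRUE,
                       digits = 15)
  unname(tools::md5sum(tf))
}
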