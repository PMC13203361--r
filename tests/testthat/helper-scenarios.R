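# Shared fixtures: reduced-grid (0.2 mm) runs of the default scenario,
# built once per test session and reused across files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

test_cfg <- function(dx_mm = 0.2) {
  cfg <- load_config()
  cfg$transport$dx_mm <- dx_mm
  cfg
}

test_objects <- function() memo("objects", {
  magcellflow:::config_objects(test_cfg())
})

# field grid of the default magnet/placement on the 0.2 mm chamber grid
test_fg <- function() memo("fg", {
  ob <- test_objects()
  field_grid(ob$magnet, ob$placement, ob$chamber, spacing = ob$params$dx)
})

# no-magnet reference run at a given inlet speed
test_ref <- function(dUx_mm_s = 0.2) memo(paste0("ref_", dUx_mm_s), {
  ob <- test_objects()
  simulate_scenario(ob$chamber, NULL, ob$placement,
                    cell_model(n_spions = 0), fluid_spec(0.0011,
                                                         dUx_mm_s * 1e-3),
                    ob$params,
                    snapshot_times = ob$params$t_end * c(0.7, 0.8, 0.9, 1))
})

# magnet-on run for a given d_mag (um) and inlet speed
test_run <- function(d_mag_um, dUx_mm_s = 0.2) {
  memo(sprintf("run_%s_%s", d_mag_um, dUx_mm_s), {
    ob <- test_objects()
    simulate_scenario(ob$chamber, ob$magnet, ob$placement,
                      cell_model(d_mag = d_mag_um * 1e-6),
                      fluid_spec(0.0011, dUx_mm_s * 1e-3), ob$params,
                      fg = test_fg(),
                      snapshot_times = ob$params$t_end * c(0.7, 0.8, 0.9, 1))
  })
}

# loading-indexed run (SPIONs/cell) at the default speed
test_run_loading <- function(loading) {
  test_run(equivalent_magnetic_diameter(loading) * 1e6)
}

test_curve <- function() memo("curve", build_calibration(test_cfg()))

# noiseless rendered stacks of the 1e6 run and its reference
test_camera0 <- function() camera_model(shot_noise = FALSE,
                                        read_noise_sd = 0)
test_stack <- function() memo("stack", {
  render_frames(test_run_loading(1e6)$sol, test_camera0(), seed = 101)
})
test_ref_stack <- function() memo("ref_stack", {
  render_frames(test_ref()$sol, test_camera0(), seed = 102)
})

# tiny camera for fast noise statistics tests (2 x 2 mm at 0.1 mm/px)
tiny_camera <- function(...) {
  camera_model(pixel_size = 0.1e-3, fov = c(2e-3, 2e-3),
               fov_origin = c(10e-3, 6e-3), ...)
}

# minimal synthetic transport_solution carrying an arbitrary field snapshot
fake_solution <- function(cfield, chamber = chamber_spec(), h = 2e-4,
                          times = 1) {
  g <- magcellflow:::chamber_grid(chamber, h)
  stopifnot(all(dim(cfield) == c(g$nx, g$ny)))
  structure(list(x = g$x, y = g$y, h = h,
                 conc = rep(list(cfield), length(times)), times = times,
                 final = cfield, dt = 1,
                 mass = data.frame(time = times, mass = sum(cfield) * h^2,
                                   influx = 0, outflux = 0),
                 chamber = chamber,
                 params = transport_params(dx = h, t_end = max(times))),
            class = "transport_solution")
}
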