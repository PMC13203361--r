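# Plume transport: conservation, positivity, characteristics oracle,
# Lagrangian twin, deflection metric and magnet-shift transmission.

test_that("empty boundary conditions keep the field identically zero", {
  ch <- chamber_spec()
  vel <- velocity_field(ch, NULL, cell_model(n_spions = 0), fluid_spec(
    inlet_speed_dUx = 0), spacing = 1e-3)
  sol <- solve_transport(ch, transport_params(diffusivity_D = 0, dx = 1e-3,
                                              t_end = 10, inlet_conc = 0),
                         vel)
  expect_true(all(sol$final == 0))
})

test_that("pure advection moves a pulse at dUx (characteristics oracle)", {
  ch <- chamber_spec()
  h <- 2e-4
  vel <- velocity_field(ch, NULL, cell_model(n_spions = 0),
                        fluid_spec(inlet_speed_dUx = 0.2e-3), spacing = h)
  g <- magcellflow:::chamber_grid(ch, h)
  c0 <- outer(exp(-((g$x - 5e-3) / 1e-3)^2),
              exp(-((g$y - 7e-3) / 1e-3)^2))
  t_end <- 50
  sol <- solve_transport(ch, transport_params(diffusivity_D = 0, dx = h,
                                              t_end = t_end,
                                              inlet_conc = 0),
                         vel, c0 = c0)
  cx <- function(m) sum(m * outer(g$x, rep(1, g$ny))) / sum(m)
  # method of characteristics: x(t) = x(0) + dUx * t exactly
  expect_equal(cx(sol$final), cx(c0) + 0.2e-3 * t_end, tolerance = h / 2)
  # mass is conserved (pulse far from boundaries)
  expect_equal(sum(sol$final), sum(c0), tolerance = 1e-10)
})

test_that("mass bookkeeping closes to 1e-6 relative each step", {
  sol <- test_run(1.6)$sol
  ms <- sol$mass
  dmass <- diff(c(0, ms$mass))
  resid <- abs(dmass - (ms$influx - ms$outflux) * sol$dt)
  expect_lt(max(resid / (ms$influx * sol$dt)), 1e-6)
})

test_that("upwind solution stays non-negative; bounded for plug flow", {
  expect_true(all(test_run(1.6)$sol$final >= 0))
  ref <- test_ref()$sol
  expect_true(all(ref$final >= 0))
  # divergence-free (no magnet) transport obeys the inlet bound
  expect_lte(max(ref$final), 1 * (1 + 1e-9))
})

test_that("time steps violating the stability bound are rejected by name", {
  ch <- chamber_spec()
  vel <- velocity_field(ch, NULL, cell_model(n_spions = 0),
                        fluid_spec(inlet_speed_dUx = 0.2e-3),
                        spacing = 1e-3)
  err <- tryCatch(solve_transport(ch, transport_params(dx = 1e-3, dt = 60,
                                                       t_end = 120), vel),
                  error = conditionMessage)
  expect_match(err, "stability bound")
  expect_match(err, "use dt <=")
})

test_that("velocity field is plug flow without magnetic slip", {
  ch <- chamber_spec()
  fl <- fluid_spec(inlet_speed_dUx = 0.3e-3)
  v0 <- velocity_field(ch, NULL, cell_model(d_mag = 0), fl, spacing = 1e-3)
  expect_true(all(v0$vx == 0.3e-3) && all(v0$vy == 0))
  fg0 <- field_grid(magnet_spec(remanence_Br = 0), magnet_placement(), ch,
                    spacing = 1e-3)
  vB0 <- velocity_field(ch, fg0, cell_model(d_mag = 1.6e-6), fl,
                        spacing = 1e-3)
  expect_true(all(vB0$vx == 0.3e-3) && all(vB0$vy == 0))
})

test_that("lateral slip points toward the magnet everywhere", {
  vel <- test_run(1.6)$vel
  expect_true(all(vel$vy > 0))
})

test_that("trajectories integrate the velocity field accurately", {
  # no magnet: straight line at dUx
  ch <- chamber_spec()
  vel <- velocity_field(ch, NULL, cell_model(n_spions = 0),
                        fluid_spec(inlet_speed_dUx = 0.4e-3),
                        spacing = 1e-3)
  tr <- trace_trajectory(c(1e-3, 7e-3), vel, dt = 1, t_max = 200)
  expect_equal(tr$exit_flag, "outflow")
  expect_true(all(abs(tr$positions[, 2] - 7e-3) < 1e-12))
  expect_equal(diff(tr$positions[1:2, 1]), 0.4e-3, tolerance = 1e-12)
  expect_error(trace_trajectory(c(-1e-3, 7e-3), vel), "outside")
  # halving dt changes the exit point by far less than 1% of the width
  vel16 <- test_run(1.6)$vel
  t1 <- trace_trajectory(c(1e-4, 7e-3), vel16, dt = 0.4, t_max = 600)
  t2 <- trace_trajectory(c(1e-4, 7e-3), vel16, dt = 0.2, t_max = 600)
  e1 <- t1$positions[nrow(t1$positions), ]
  e2 <- t2$positions[nrow(t2$positions), ]
  expect_lt(sqrt(sum((e1 - e2)^2)), 0.01 * 14e-3)
})

test_that("Lagrangian trajectory tracks the Eulerian plume ridge", {
  for (dm in c(1.0, 1.6)) {
    run <- test_run(dm)
    tr <- trace_trajectory(c(1e-4, 7e-3), run$vel, dt = 0.2, t_max = 600)
    ix <- which(tr$positions[, 1] >= 25e-3)[1]
    ty <- stats::approx(tr$positions[(ix - 1):ix, 1],
                        tr$positions[(ix - 1):ix, 2], 25e-3)$y
    iy <- which.min(abs(run$sol$x - 25e-3))
    col <- run$sol$final[iy, ]
    cy <- sum(col * run$sol$y) / sum(col)
    expect_lt(abs(ty - cy), run$sol$h)     # within one grid cell
  }
})

test_that("doubling the inlet speed reduces the lateral displacement", {
  tr2 <- trace_trajectory(c(1e-4, 7e-3), test_run(1.6, 0.2)$vel,
                          dt = 0.2, t_max = 900)
  tr5 <- trace_trajectory(c(1e-4, 7e-3), test_run(1.6, 0.5)$vel,
                          dt = 0.2, t_max = 900)
  disp <- function(tr) max(tr$positions[, 2]) - 7e-3
  expect_gt(disp(tr2), disp(tr5))
})

test_that("deflection metric: identity, magnet-pull ordering, flags", {
  ref <- test_ref()$sol
  expect_equal(deflection_metric(ref, ref, 25e-3)$drift, 0)
  expect_equal(deflection_metric(ref, ref, 25e-3)$angle, 0)
  # drift strictly increases with d_mag at 0.2 mm/s (Figure-4 ordering)
  drifts <- sapply(c(1.0, 1.2, 1.4, 1.6), function(dm)
    deflection_metric(test_run(dm)$sol, ref, 25e-3)$drift)
  expect_true(all(diff(drifts) > 0))
  expect_gt(drifts[4], 2e-3)               # strong turning for large d_mag
  # faster flow carries the plume past the magnet: smaller drift
  ref5 <- test_ref(0.5)$sol
  d5 <- deflection_metric(test_run(1.0, 0.5)$sol, ref5, 25e-3)$drift
  expect_lt(d5, drifts[1])
  # plume not yet at the station: flagged not measurable
  ob <- test_objects()
  early <- simulate_scenario(ob$chamber, NULL, ob$placement,
                             cell_model(n_spions = 0), ob$fluid,
                             transport_params(dx = 2e-4, t_end = 5))$sol
  expect_false(deflection_metric(early, early, 25e-3)$measurable)
})

test_that("halving the grid spacing changes the station drift by < 5%", {
  cfg1 <- test_cfg(0.1)
  ob <- magcellflow:::config_objects(cfg1)
  fg <- field_grid(ob$magnet, ob$placement, ob$chamber, spacing = 1e-4)
  ref <- simulate_scenario(ob$chamber, NULL, ob$placement,
                           cell_model(n_spions = 0), ob$fluid, ob$params)$sol
  sol <- simulate_scenario(ob$chamber, ob$magnet, ob$placement,
                           cell_model(n_spions = 1e6), ob$fluid, ob$params,
                           fg = fg)$sol
  fine <- deflection_metric(sol, ref, 25e-3)$drift
  coarse <- deflection_metric(test_run_loading(1e6)$sol, test_ref()$sol,
                              25e-3)$drift
  expect_lt(abs(coarse - fine) / fine, 0.05)
})

test_that("accumulation tracks a magnet shift; degenerate cases flagged", {
  base <- test_run(1.6)$sol
  tc0 <- transmission_coefficient(base, base, c(0, 0))
  expect_true(tc0$flagged)
  # no magnet: no accumulation detected
  tcn <- transmission_coefficient(test_ref()$sol, base, c(1e-3, 0))
  expect_true(tcn$flagged)
  # +1 mm along the flow axis: roughly 1:1 transmission
  ob <- test_objects()
  pl26 <- magnet_placement(26e-3, 5e-3)
  fg26 <- memo("fg26", field_grid(ob$magnet, pl26, ob$chamber,
                                  spacing = 2e-4))
  s26 <- memo("run26", simulate_scenario(ob$chamber, ob$magnet, pl26,
                                         cell_model(d_mag = 1.6e-6),
                                         ob$fluid, ob$params, fg = fg26))
  tc1 <- transmission_coefficient(base, s26$sol, c(1e-3, 0))
  expect_false(tc1$flagged)
  expect_equal(tc1$ratio, 1, tolerance = 0.2)
  # +5 mm: same-direction displacement (outlet-limited, see vignette)
  pl30 <- magnet_placement(30e-3, 5e-3)
  fg30 <- field_grid(ob$magnet, pl30, ob$chamber, spacing = 2e-4)
  s30 <- simulate_scenario(ob$chamber, ob$magnet, pl30,
                           cell_model(d_mag = 1.6e-6), ob$fluid, ob$params,
                           fg = fg30)
  tc5 <- transmission_coefficient(base, s30$sol, c(5e-3, 0))
  expect_false(tc5$flagged)
  expect_gt(tc5$ratio, 0)
})
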