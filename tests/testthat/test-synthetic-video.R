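# Synthetic fluorescence rendering: determinism, noise statistics,
# resampling fidelity, sparse-cell spots and disk round trips.

test_that("zero concentration with noise off gives a flat background", {
  ch <- chamber_spec()
  cam <- tiny_camera(shot_noise = FALSE, read_noise_sd = 0)
  g <- magcellflow:::chamber_grid(ch, 2e-4)
  sol <- fake_solution(matrix(0, g$nx, g$ny))
  st <- render_frames(sol, cam, seed = 1)
  expect_true(all(st$frames[[1]] == cam$background))
  expect_false(any(st$masks[[1]]))
})

test_that("rendering is seed-deterministic; masks are noise-independent", {
  sol <- test_run_loading(1e6)$sol
  cam <- tiny_camera()
  a <- render_frames(sol, cam, seed = 7)
  b <- render_frames(sol, cam, seed = 7)
  c <- render_frames(sol, cam, seed = 8)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
  expect_identical(a$masks, c$masks)
})

test_that("noiseless mask centroid matches the concentration centroid", {
  ch <- chamber_spec()
  g <- magcellflow:::chamber_grid(ch, 2e-4)
  blob <- outer(exp(-((g$x - 16e-3) / 1.5e-3)^2),
                exp(-((g$y - 7e-3) / 1.5e-3)^2))
  sol <- fake_solution(blob)
  cam <- camera_model(shot_noise = FALSE, read_noise_sd = 0)
  st <- render_frames(sol, cam, seed = 1)
  m <- st$masks[[1]]
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  cx_mm <- cam$fov_origin[1] * 1e3 +
    (sum(m * cols) / sum(m) - 0.5) * cam$pixel_size * 1e3
  cy_mm <- cam$fov_origin[2] * 1e3 +
    (sum(m * rows) / sum(m) - 0.5) * cam$pixel_size * 1e3
  # the 10% mask of a symmetric blob is centred on the blob
  expect_lt(abs(cx_mm - 16), cam$pixel_size * 1e3)
  expect_lt(abs(cy_mm - 7), cam$pixel_size * 1e3)
})

test_that("noisy frame means match the noiseless frame within 3 SE", {
  ch <- chamber_spec()
  g <- magcellflow:::chamber_grid(ch, 2e-4)
  blob <- 0.5 * outer(exp(-((g$x - 11e-3) / 1e-3)^2),
                      exp(-((g$y - 7e-3) / 1e-3)^2))
  sol <- fake_solution(blob)
  clean <- render_frames(sol, tiny_camera(shot_noise = FALSE,
                                          read_noise_sd = 0), seed = 1)
  cam <- tiny_camera()
  means <- vapply(seq_len(100), function(s)
    mean(render_frames(sol, cam, seed = s)$frames[[1]]), numeric(1))
  target <- mean(clean$frames[[1]])
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * se + 0.5)  # 0.5: rounding bias
})

test_that("sparse cells render as tracking Gaussian spots", {
  cam <- camera_model(pixel_size = 0.05e-3, fov = c(10e-3, 8e-3),
                      fov_origin = c(2e-3, 3e-3), shot_noise = FALSE,
                      read_noise_sd = 0)
  # static cell: identical spot in every frame
  static <- structure(list(times = c(0, 10),
                           positions = rbind(c(5e-3, 6e-3), c(5e-3, 6e-3)),
                           exit_flag = "interior"), class = "trajectory")
  st <- render_sparse_cells(list(static), cam, timestamps = c(1, 5, 9))
  expect_identical(st$frames[[1]], st$frames[[2]])
  expect_identical(st$frames[[2]], st$frames[[3]])
  # moving cell: spot centroid tracks the trajectory within 0.5 px
  moving <- structure(list(times = c(0, 10),
                           positions = rbind(c(3e-3, 4e-3),
                                             c(9e-3, 8e-3)),
                           exit_flag = "interior"), class = "trajectory")
  st2 <- render_sparse_cells(list(moving), cam, timestamps = c(2.5, 7.5))
  for (k in 1:2) {
    f <- st2$frames[[k]] - cam$background
    rows <- matrix(seq_len(nrow(f)), nrow(f), ncol(f))
    cols <- matrix(seq_len(ncol(f)), nrow(f), ncol(f), byrow = TRUE)
    cx <- sum(f * cols) / sum(f)
    cy <- sum(f * rows) / sum(f)
    tpos <- c(stats::approx(moving$times, moving$positions[, 1],
                            st2$timestamps[k])$y,
              stats::approx(moving$times, moving$positions[, 2],
                            st2$timestamps[k])$y)
    exp_px <- (tpos - cam$fov_origin) / cam$pixel_size + 0.5
    expect_lt(abs(cx - exp_px[1]), 0.5)
    expect_lt(abs(cy - exp_px[2]), 0.5)
  }
  # non-overlapping cells: mask area is additive
  far <- structure(list(times = c(0, 10),
                        positions = rbind(c(10e-3, 9e-3), c(10e-3, 9e-3)),
                        exit_flag = "interior"), class = "trajectory")
  one <- render_sparse_cells(list(static), cam, timestamps = 5)
  two <- render_sparse_cells(list(static, far), cam, timestamps = 5)
  expect_equal(sum(two$masks[[1]]), 2 * sum(one$masks[[1]]),
               tolerance = 0.05)
})

test_that("a field of view outside the chamber is rejected", {
  sol <- test_run_loading(1e6)$sol
  cam <- camera_model(fov_origin = c(20e-3, 2e-3))  # runs past x = 32 mm
  expect_error(render_frames(sol, cam), "outside the chamber")
})

test_that("frame stacks round-trip through TIFF + JSON", {
  sol <- test_run_loading(1e6)$sol
  cam <- tiny_camera()
  st <- render_frames(sol, cam, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "stack")
  write_frame_stack(st, prefix)
  rt <- read_frame_stack(prefix)
  expect_equal(rt$frames, st$frames)
  expect_identical(lapply(rt$masks, unname), lapply(st$masks, unname))
  expect_equal(rt$timestamps, st$timestamps)
  expect_equal(rt$camera$gain, cam$gain)
})
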