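# Segmentation backends, mask metrics, descriptor extraction, QC filtering
# and replicate summaries.

test_that("uniform frames segment to an empty mask", {
  f <- matrix(200, 40, 60)
  expect_false(any(segment_frame(f)))
  expect_false(any(segment_frame(f, otsu_backend())))
})

test_that("segmentation of a noiseless plume frame hits the ground truth", {
  st <- test_stack()
  k <- length(st$frames)
  mask <- segment_frame(st$frames[[k]])
  expect_gte(iou(mask, st$masks[[k]]), 0.95)
  expect_gte(recall(mask, st$masks[[k]]), 0.95)
})

test_that("the default threshold is invariant to a constant offset", {
  st <- test_stack()
  f <- st$frames[[length(st$frames)]]
  expect_identical(segment_frame(f), segment_frame(f + 500))
})

test_that("otsu threshold splits a bimodal histogram between the modes", {
  set.seed(1)
  x <- c(rnorm(4000, 100, 5), rnorm(4000, 200, 5))
  thr <- otsu_threshold(x)
  # the objective is flat across the empty gap; any split separating the
  # modes is a valid argmax
  expect_gt(thr, 110)
  expect_lt(thr, 190)
  expect_true(is.na(otsu_threshold(rep(3, 10))))
})

test_that("IoU and recall follow their set definitions", {
  a <- matrix(FALSE, 20, 20); a[6:15, 6:15] <- TRUE       # 10 x 10 square
  expect_equal(iou(a, a), 1)
  expect_equal(recall(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[1:3, 1:3] <- TRUE
  expect_equal(iou(a, b), 0)
  # square shifted by half its side: overlap 50, union 150
  s <- matrix(FALSE, 20, 20); s[6:15, 11:20] <- TRUE
  expect_equal(iou(a, s), 1 / 3)
  expect_equal(recall(s, a), 1 / 2)
  e <- matrix(FALSE, 20, 20)
  expect_equal(iou(e, e), 1)            # both empty: defined as 1
  expect_equal(recall(e, e), 1)
  expect_error(iou(a, matrix(FALSE, 5, 5)), "shapes differ")
  expect_true(all(sapply(list(iou(a, s), recall(s, a)),
                         function(v) v >= 0 && v <= 1)))
})

test_that("descriptors recover a known centred square", {
  cam <- camera_model(pixel_size = 0.1e-3, fov = c(4e-3, 4e-3),
                      fov_origin = c(0, 0), shot_noise = FALSE,
                      read_noise_sd = 0)
  f <- matrix(100, 40, 40)
  f[16:25, 16:25] <- 4000
  stack <- structure(list(frames = list(f, f), masks = NULL,
                          timestamps = c(0, 1), camera = cam, seed = 1),
                     class = "frame_stack")
  d <- extract_descriptors(stack, reference_frames = 2)
  expect_equal(d$cx_px, c(20.5, 20.5))
  expect_equal(d$cy_px, c(20.5, 20.5))
  expect_equal(d$area_mm2, c(1, 1))
  # identical to its own reference: zero drift and angle
  expect_equal(d$drift_mm, c(0, 0))
  expect_equal(d$angle_deg, c(0, 0))
  expect_equal(d$rate_mm_s[2], 0)
})

test_that("end-to-end video drift matches the simulated deflection within 1 px", {
  sim <- deflection_metric(test_run_loading(1e6)$sol, test_ref()$sol,
                           25e-3)$drift * 1e3
  md <- measure_drift(test_stack(), test_ref_stack(), 25)
  px <- test_stack()$camera$pixel_size * 1e3
  expect_lt(abs(md$drift_mm - sim), px)
})

test_that("QC filtering rejects frames for the documented reasons", {
  d <- data.frame(frame_id = 1:5, time = 0:4,
                  cx_px = 50, cy_px = 50,
                  cx_mm = 10, cy_mm = c(7, 7.1, 12.5, 7.2, 7.3),
                  area_mm2 = c(5, 0.1, 5, 5, 5), quality = 1,
                  qc_pass = TRUE, qc_reason = "",
                  drift_mm = 0, angle_deg = 0, rate_mm_s = 0)
  qc <- qc_filter(d, min_area_mm2 = 0.5, max_jump_mm = 2)
  expect_equal(qc$rejected$frame_id, c(2, 3))
  expect_equal(qc$rejected$qc_reason, c("low-area", "centroid-jump"))
  expect_equal(qc$accepted$frame_id, c(1, 4, 5))
  # all-valid input: nothing rejected
  d2 <- d; d2$area_mm2 <- 5; d2$cy_mm <- 7
  expect_equal(nrow(qc_filter(d2)$rejected), 0)
  # quality gate
  d3 <- d2; d3$quality <- c(1, 1, 0.2, 1, 1)
  qc3 <- qc_filter(d3, min_quality = 0.5)
  expect_equal(qc3$rejected$qc_reason, "low-quality")
  # empty-mask frames carry their reason through
  d4 <- d2; d4$qc_pass[4] <- FALSE; d4$qc_reason[4] <- "empty"
  expect_equal(qc_filter(d4)$rejected$qc_reason, "empty")
})

test_that("descriptor summaries report mean, sd and cv per replicate", {
  d <- data.frame(drift_mm = c(1, 3), angle_deg = c(2, 2),
                  area_mm2 = c(4, 4), rate_mm_s = c(1, 1))
  s <- summarize_descriptors(d)
  row <- s[s$replicate == "pooled" & s$variable == "drift_mm", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, sqrt(2))
  expect_equal(row$cv, sqrt(2) / 2)
  # identical frames: zero spread
  dz <- d; dz$drift_mm <- c(2, 2)
  sz <- summarize_descriptors(dz)
  expect_equal(sz$sd[sz$variable == "drift_mm" &
                       sz$replicate == "pooled"], 0)
  # pooled mean equals the n-weighted replicate means
  dr <- data.frame(drift_mm = c(1, 3, 5, 7, 9),
                   angle_deg = 0, area_mm2 = 1, rate_mm_s = 0,
                   replicate = c(1, 1, 2, 2, 2))
  sr <- summarize_descriptors(dr)
  g <- sr[sr$variable == "drift_mm", ]
  pooled <- g$mean[g$replicate == "pooled"]
  reps <- g[g$replicate != "pooled", ]
  expect_equal(pooled, sum(reps$mean * reps$n) / sum(reps$n))
  expect_error(summarize_descriptors(d[0, ]), "no measurable")
})

test_that("drift reproducibility across noise seeds is tight at high loading", {
  # cv of the measured drift over seeds stays under 10% at 5e5 SPIONs/cell
  sol <- test_run_loading(5e5)$sol
  ref <- test_ref()$sol
  cam <- camera_model()
  drifts <- vapply(1:10, function(s) {
    st <- render_frames(sol, cam, seed = 300 + 2 * s)
    rt <- render_frames(ref, cam, seed = 301 + 2 * s)
    measure_drift(st, rt, 25)$drift_mm
  }, numeric(1))
  expect_lt(stats::sd(drifts) / mean(drifts), 0.10)
})
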