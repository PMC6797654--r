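identity_model <- function() {
  m <- five_point_manifest()
  fit_calibration(tibble::tibble(
    target_id = m$target_id, x_raw = m$target_x_deg,
    y_raw = m$target_y_deg, target_x_deg = m$target_x_deg,
    target_y_deg = m$target_y_deg
  ))
}

calibrated_sine <- function(A = 2, f = 2, dur_s = 3, noise = 0) {
  t <- 0:(dur_s * 1000 - 1)
  set.seed(41)
  rec <- gaze_recording(t, A * sin(2 * pi * f * t / 1000),
                        rnorm(length(t), 0, noise + 1e-6))
  fs <- filter_gaze(rec, axis = "horizontal")
  apply_calibration(identity_model(), fs)
}

test_that("classic foveation durations match the analytic sine solution", {
  A <- 2; f <- 2; v <- 4
  cal <- calibrated_sine(A, f)
  runs <- classic_foveation_detect(cal, v_thresh = v, min_dur_ms = 7)
  # speed 2 pi f A |cos| < v around each extremum: asin(r) / (pi f)
  expected_ms <- asin(v / (2 * pi * f * A)) / (pi * f) * 1000
  interior <- runs[runs$start > 100 & runs$end < nrow(cal) - 100, ]
  expect_gt(nrow(interior), 5)
  expect_lt(max(abs(interior$duration_ms - expected_ms)), 2)
})

test_that("a constant trace is one single foveation run", {
  t <- 0:999
  rec <- gaze_recording(t, rep(1, 1000), rep(0, 1000))
  cal <- apply_calibration(identity_model(), filter_gaze(rec))
  runs <- classic_foveation_detect(cal, v_thresh = 4)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end), c(1L, 1001L))
})

test_that("the position window rejects displaced runs", {
  # two low-speed plateaus at +0.2 and +1.5 deg joined by a fast ramp
  x <- c(rep(0.2, 300), seq(0.2, 1.5, length.out = 100), rep(1.5, 100),
         rep(0.2, 500))
  t <- seq_along(x) - 1
  cal <- apply_calibration(identity_model(),
                           filter_gaze(gaze_recording(t, x, rep(0, length(x))),
                                       axis = "horizontal"))
  with_window <- classic_foveation_detect(cal, v_thresh = 4,
                                          pos_window_deg = 0.5)
  without <- classic_foveation_detect(cal, v_thresh = 4)
  expect_gt(nrow(without), nrow(with_window))
  expect_true(all(abs(with_window$mean_x_deg - 0.2) < 0.1))
  expect_false(all(abs(without$mean_x_deg - 0.2) < 0.1))
})

test_that("classic durations are monotone in the velocity threshold", {
  cal <- calibrated_sine(2, 2)
  total <- vapply(c(1, 2, 4, 8), function(v) {
    sum(classic_foveation_detect(cal, v_thresh = v)$duration_ms)
  }, numeric(1))
  expect_true(all(diff(total) >= 0))
})

test_that("intensity is amplitude times frequency", {
  cal <- calibrated_sine(2, 3)  # peak-to-trough 4 deg, 3 Hz
  fs <- filter_gaze(gaze_recording(cal$t_ms, cal$x_deg, cal$y_deg),
                    axis = "horizontal")
  cycles <- split_cycles(fs)
  met <- nystagmus_metrics(cal, cycles)
  expect_equal(met$intensity, met$amplitude * met$frequency_hz)
  expect_equal(met$amplitude, 4, tolerance = 0.05)
  expect_equal(met$frequency_hz, 3, tolerance = 0.05)

  expect_error(nystagmus_metrics(cal, cycles[0, ]), "no cycles")
})

test_that("simulated jerk metrics are within 10% of ground truth", {
  ses <- sim_fixation(amplitude = 4, frequency = 3, dwell_ms = 6000,
                      seed = 43, blinks = 0)
  seg <- segment_waveform(ses$recording)
  model <- fit_calibration(affine_por())  # same transform as simulator
  cal <- apply_calibration(model, seg$fs)
  met <- nystagmus_metrics(cal, seg$cycles)
  expect_equal(met$amplitude, 4, tolerance = 0.1 * 4)
  expect_equal(met$frequency_hz, 3, tolerance = 0.1 * 3)
  expect_equal(met$intensity, 12, tolerance = 0.1 * 12)
})

test_that("nonselective POR is the plain interval median", {
  t <- 0:999
  rec <- gaze_recording(t, 3 + 2 * sin(2 * pi * 4 * t / 1000),
                        rep(1, 1000))
  target <- tibble::tibble(target_id = 1, target_x_deg = 0,
                           target_y_deg = 0, start_ms = 0, end_ms = 1000)
  por <- nonselective_por(rec, target, skip_initial_ms = 0)
  expect_equal(por$x_raw, 3, tolerance = 0.01)  # symmetry about the centre

  rec2 <- gaze_recording(0:3, c(0, 0, 0, 10), rep(0, 4),
                         min_rate_hz = 100)
  t2 <- tibble::tibble(target_id = 1, target_x_deg = 0, target_y_deg = 0,
                       start_ms = 0, end_ms = 4)
  expect_equal(nonselective_por(rec2, t2, 0)$x_raw, 0)

  # permutation invariance
  set.seed(44)
  perm <- sample(1000)
  rec3 <- rec
  rec3$x <- rec$x[perm]
  rec3$y <- rec$y[perm]
  expect_equal(nonselective_por(rec3, target, 0)$x_raw,
               nonselective_por(rec, target, 0)$x_raw)
})

test_that("method comparison reports errors in deg and % of amplitude", {
  ref <- tibble::tibble(target_id = 1, x_raw = 0, y_raw = 0)
  alg <- tibble::tibble(target_id = 1, x_raw = 0.21, y_raw = 0)
  non <- tibble::tibble(target_id = 1, x_raw = 0.83, y_raw = 0)
  out <- compare_methods(alg, non, ref, identity_model(),
                         amplitude_deg = 6.3)
  expect_equal(out$algorithmic_deg, 0.21, tolerance = 1e-9)
  expect_equal(out$nonselective_deg, 0.83, tolerance = 1e-9)
  expect_equal(out$difference_deg, 0.62, tolerance = 1e-9)
  expect_equal(out$algorithmic_pct, 100 * 0.21 / 6.3, tolerance = 1e-9)

  same <- compare_methods(ref, ref, ref, identity_model(), 4)
  expect_equal(same$algorithmic_deg, 0)
  expect_equal(same$difference_pct, 0)
})
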