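test_that("linear model with cross-talk inverts affine maps exactly", {
  model <- fit_calibration(affine_por(theta_deg = 0))
  expect_lt(max(model$residuals$resid_deg), 1e-9)
  # pure scaling: no cross-talk needed, term is zero
  expect_lt(abs(model$coef$x[["y_raw"]]), 1e-12)
})

test_that("the cross-talk term absorbs rotation of the calibration field", {
  for (theta in c(5, 10)) {
    model <- fit_calibration(affine_por(theta_deg = theta))
    expect_lt(max(model$residuals$resid_deg), 1e-9)
    expect_gt(abs(model$coef$x[["y_raw"]]), 1e-6)
  }
})

test_that("degenerate designs fail loudly", {
  por <- affine_por()
  por$x_raw <- por$x_raw[1]
  por$y_raw <- por$y_raw[1]
  expect_error(fit_calibration(por), "rank-deficient")
  expect_error(fit_calibration(affine_por()[1:2, ]), "at least 3 targets")
  expect_error(fit_calibration(affine_por(), order = "quadratic"),
               "at least 6 targets")
})

test_that("translating raw inputs changes only the intercepts", {
  por <- affine_por(theta_deg = 7)
  m1 <- fit_calibration(por)
  por2 <- por
  por2$x_raw <- por2$x_raw + 111
  por2$y_raw <- por2$y_raw - 55
  m2 <- fit_calibration(por2)
  for (ax in c("x", "y")) {
    expect_equal(m2$coef[[ax]][c("x_raw", "y_raw")],
                 m1$coef[[ax]][c("x_raw", "y_raw")], tolerance = 1e-9)
  }
  expect_false(isTRUE(all.equal(m2$coef$x[["(Intercept)"]],
                                m1$coef$x[["(Intercept)"]])))
})

test_that("applying the model to its fitted PORs reproduces the residuals", {
  ses <- sim_fixation(seed = 31, dwell_ms = 3000)
  cal <- calibrate_session(
    simulate_session(waveform_spec("jerk"), seed = 31)$recording,
    five_point_manifest()
  )
  por <- cal$por
  out <- apply_calibration(cal$model,
                           tibble::tibble(t_ms = seq_len(nrow(por)),
                                          x = por$x_raw, y = por$y_raw,
                                          valid = TRUE))
  resid <- sqrt((out$x_deg - por$target_x_deg)^2 +
                  (out$y_deg - por$target_y_deg)^2)
  expect_equal(resid, cal$model$residuals$resid_deg, tolerance = 1e-12)
})

test_that("identity raw frame round-trips through calibration", {
  por <- affine_por(gx = 1, gy = 1, bx = 0, by = 0)
  model <- fit_calibration(por)
  t <- 0:99
  rec <- tibble::tibble(t_ms = t, x = sin(t / 10), y = cos(t / 10),
                        valid = TRUE)
  out <- apply_calibration(model, rec)
  expect_equal(out$x_deg, rec$x, tolerance = 1e-9)
  expect_equal(out$y_deg, rec$y, tolerance = 1e-9)
  expect_identical(out$valid, rec$valid)
  expect_identical(out$t_ms, rec$t_ms)
})

test_that("full simulated session calibrates within 0.25 deg RMS", {
  ses <- simulate_session(waveform_spec("jerk"), seed = 33)
  cal <- calibrate_session(ses$recording, ses$manifest)
  out <- apply_calibration(cal$model, cal$fs)
  # RMS over the true-foveation samples, where gaze should be on target
  idx <- unlist(lapply(seq_len(nrow(ses$true_foveations)), function(i) {
    ses$true_foveations$start[i]:(ses$true_foveations$end[i] - 1L)
  }))
  idx <- idx[cal$fs$valid[idx]]
  err2 <- (out$x_deg[idx] - ses$truth$x_deg_true[idx])^2 +
    (out$y_deg[idx] - ses$truth$y_deg_true[idx])^2
  expect_lt(sqrt(mean(err2)), 0.25)
})

test_that("drift correction undoes a constant raw offset exactly", {
  # noiseless extended-foveation waveform: the plateau puts the POR
  # exactly at the fixation position, so the correction is exact
  base <- sim_fixation(kind = "jerk_extended_foveation", dwell_ms = 4000,
                       seed = 35, blinks = 0,
                       extended_foveation_ms = 60)
  model <- fit_calibration(affine_por())  # exact model, same transform
  drift <- c(dx = 37.5, dy = -12.25)      # raw units
  rec <- base$recording
  rec$x <- rec$x + drift[["dx"]]
  rec$y <- rec$y + drift[["dy"]]
  # suppress the noise for exactness: rebuild noiseless via truth
  raw_true <- base$transform$apply(cbind(base$truth$x_deg_true,
                                         base$truth$y_deg_true))
  rec$x <- raw_true[, 1] + drift[["dx"]]
  rec$y <- raw_true[, 2] + drift[["dy"]]
  corrected <- drift_correct(model, rec, target_deg = c(0, 0),
                             skip_initial_ms = 300)
  seg <- segment_waveform(rec)
  por <- point_of_regard(seg$fs, seg$foveations,
                         tibble::tibble(target_id = 1, target_x_deg = 0,
                                        target_y_deg = 0, start_ms = 0,
                                        end_ms = max(rec$t_ms) + 1),
                         skip_initial_ms = 300)
  out <- apply_calibration(corrected,
                           tibble::tibble(t_ms = 1, x = por$x_raw,
                                          y = por$y_raw, valid = TRUE))
  expect_lt(abs(out$x_deg), 1e-6)
  expect_lt(abs(out$y_deg), 1e-6)

  # zero drift on the same recording: model numerically unchanged
  rec0 <- rec
  rec0$x <- raw_true[, 1]
  rec0$y <- raw_true[, 2]
  same <- drift_correct(model, rec0, target_deg = c(0, 0),
                        skip_initial_ms = 300)
  expect_equal(same$coef$x, model$coef$x, tolerance = 1e-9)
  expect_equal(same$coef$y, model$coef$y, tolerance = 1e-9)
})

test_that("drift correction differs from a whole-trace median correction", {
  ses <- sim_fixation(amplitude = 4, dwell_ms = 4000, seed = 36,
                      blinks = 0)  # asymmetric jerk
  model <- fit_calibration(affine_por())
  corrected <- drift_correct(model, ses$recording, target_deg = c(0, 0))
  med <- nonselective_por(ses$recording,
                          tibble::tibble(target_id = 1, target_x_deg = 0,
                                         target_y_deg = 0, start_ms = 0,
                                         end_ms = max(ses$recording$t_ms) + 1))
  X <- nystcal:::cal_design(med$x_raw, med$y_raw, model$order)
  off_naive <- -drop(X %*% model$coef$x)
  expect_gt(abs(corrected$drift_offset_deg[["x"]] - off_naive), 0.1)
})

test_that("tidy and glance summarise the model", {
  model <- fit_calibration(affine_por(theta_deg = 10))
  td <- tidy(model)
  expect_equal(nrow(td), 6)
  expect_setequal(unique(td$axis), c("x", "y"))
  gl <- glance(model)
  expect_equal(gl$n_targets, 5)
  expect_lt(gl$max_resid_deg, 1e-9)
  p <- autoplot(model)
  expect_s3_class(p, "ggplot")
})
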