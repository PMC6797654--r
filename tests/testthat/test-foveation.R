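test_that("window length is 10% of summed slow duration with a 7 ms floor", {
  # single slow phase of 400 ms at 1000 Hz -> 40 ms window
  expect_equal(foveation_window_samples(400, 1000), 40L)
  # two slow phases of 100 and 60 ms -> 16 ms window
  expect_equal(foveation_window_samples(160, 1000), 16L)
  # 50 ms slow phase -> 5 ms window, below the 7 ms floor
  L <- foveation_window_samples(50, 1000)
  expect_equal(L, 5L)
  expect_lt(L * 1000 / 1000, pipeline_config()$min_foveation_ms)
  # rounding to whole samples, minimum 1
  expect_equal(foveation_window_samples(3, 1000), 1L)
})

test_that("a 50 ms slow phase contributes no foveation", {
  # construct a single complete cycle whose slow phase lasts 50 ms
  n <- 120
  fs <- tibble::tibble(
    t_ms = as.numeric(0:(n - 1)),
    x = 0, y = 0, valid = TRUE,
    x_smooth = 0, y_smooth = 0,
    vel_x = 0, vel_y = 0,
    speed = c(rep(1, 30), rep(0.01, 50), rep(1, 40)),
    axis = "horizontal",
    phase = c(rep("quick", 30), rep("slow", 50), rep("quick", 40))
  )
  cycles <- tibble::tibble(cycle_id = 1L, start = 1L, peak = 50L,
                           end = 119L, complete = TRUE)
  expect_equal(nrow(detect_foveations(fs, cycles)), 0)
})

test_that("monotone speed puts the window at the slow-phase onset", {
  n <- 400
  spd <- c(rep(5, 50), seq(0.1, 2, length.out = 300), rep(5, 50))
  fs <- tibble::tibble(
    t_ms = as.numeric(0:(n - 1)), x = 0, y = 0, valid = TRUE,
    x_smooth = 1, y_smooth = 2, vel_x = 0, vel_y = 0,
    speed = spd, axis = "horizontal",
    phase = c(rep("quick", 50), rep("slow", 300), rep("quick", 50))
  )
  cycles <- tibble::tibble(cycle_id = 1L, start = 1L, peak = 200L,
                           end = 399L, complete = TRUE)
  fov <- detect_foveations(fs, cycles)
  expect_equal(nrow(fov), 1)
  expect_equal(fov$start, 51L)  # earliest slow sample
  expect_equal(fov$end - fov$start, 30L)  # 10% of 300 slow samples
})

test_that("detection equals the exhaustive search oracle across the grid", {
  n_checked <- 0
  for (A in c(2, 4, 8)) {
    for (f in c(2, 3, 5)) {
      ses <- sim_fixation(amplitude = A, frequency = f, dwell_ms = 5000,
                          seed = 100 + A * 10 + f, blinks = 1)
      seg <- segment_waveform(ses$recording)
      oracle <- brute_force_foveations(seg$fs, seg$cycles)
      expect_equal(seg$foveations$start, oracle$start)
      expect_equal(seg$foveations$end, oracle$end)
      expect_equal(seg$foveations$cycle_id, oracle$cycle_id)
      n_checked <- n_checked + nrow(oracle)
    }
  }
  expect_gt(n_checked, 100)
})

test_that("foveation windows avoid quick-phase and invalid samples", {
  ses <- sim_fixation(seed = 21, dwell_ms = 5000, blinks = 1)
  seg <- segment_waveform(ses$recording)
  for (i in seq_len(nrow(seg$foveations))) {
    w <- seg$foveations$start[i]:(seg$foveations$end[i] - 1L)
    expect_true(all(seg$fs$phase[w] == "slow"))
    expect_true(all(seg$fs$valid[w]))
  }
  # and never overlap each other
  all_idx <- unlist(lapply(seq_len(nrow(seg$foveations)), function(i) {
    seg$foveations$start[i]:(seg$foveations$end[i] - 1L)
  }))
  expect_equal(anyDuplicated(all_idx), 0)
})

test_that("window choice is scale invariant", {
  ses <- sim_fixation(seed = 22, dwell_ms = 3000, blinks = 0)
  rec <- ses$recording
  f1 <- segment_waveform(rec)$foveations
  rec$x <- rec$x * 40
  rec$y <- rec$y * 40
  f2 <- segment_waveform(rec)$foveations
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
})

test_that("sine-cycle windows sit at position extrema", {
  t <- 0:4999
  set.seed(23)
  rec <- gaze_recording(t, 3 * sin(2 * pi * 2 * t / 1000),
                        rnorm(5000, 0, 1e-3))
  seg <- segment_waveform(rec)
  fov <- seg$foveations
  expect_gt(nrow(fov), 3)
  half_period_ms <- 250
  for (i in seq_len(nrow(fov))) {
    centre <- (fov$start_ms[i] + fov$end_ms[i]) / 2
    # nearest extremum of 3 sin(2 pi 2 t): t = 125 + k * 250 ms
    dist <- min(abs(((centre - 125) %% half_period_ms)),
                half_period_ms - ((centre - 125) %% half_period_ms))
    expect_lt(dist, (fov$end_ms[i] - fov$start_ms[i]) / 2 + 1)
  }
})

test_that("POR is the per-coordinate median and needs a foveation", {
  fs <- tibble::tibble(
    t_ms = as.numeric(0:9), x = 0, y = 0, valid = TRUE,
    x_smooth = c(1, 2, 100, 0, 0, 0, 0, 0, 0, 0),
    y_smooth = c(5, 6, 7, 0, 0, 0, 0, 0, 0, 0),
    speed = 0, axis = "horizontal", phase = "slow"
  )
  fov <- tibble::tibble(cycle_id = 1L, start = 1L, end = 4L)
  target <- tibble::tibble(target_id = 1L, target_x_deg = 0,
                           target_y_deg = 0, start_ms = 0, end_ms = 10)
  por <- point_of_regard(fs, fov, target, skip_initial_ms = 0)
  expect_equal(por$x_raw, 2)   # robust to the outlier 100
  expect_equal(por$y_raw, 6)
  expect_equal(por$n_foveations, 1L)

  # single foveation: its own mean/median position
  fov1 <- tibble::tibble(cycle_id = 1L, start = 4L, end = 5L)
  expect_equal(point_of_regard(fs, fov1, target, 0)$x_raw, 0)

  # no foveation in the interval: explicit failure naming the target
  late <- tibble::tibble(target_id = 99L, target_x_deg = 0,
                         target_y_deg = 0, start_ms = 100, end_ms = 200)
  expect_error(point_of_regard(fs, fov, late, 0), "target 99")
})

test_that("POR recovers the fixation position within 5% of amplitude", {
  ses <- sim_fixation(amplitude = 4, dwell_ms = 10000, seed = 24,
                      blinks = 1)
  seg <- segment_waveform(ses$recording)
  por <- por_table(seg$fs, seg$foveations, ses$manifest)
  fix <- ses$fixations_raw
  amp_raw <- 4 * ses$transform$gain_x
  err <- sqrt((por$x_raw - fix$x_raw)^2 + (por$y_raw - fix$y_raw)^2)
  expect_lt(err, 0.05 * amp_raw)
})

test_that("pendular foveations land on both sides of the waveform", {
  ses <- sim_fixation(kind = "pendular", amplitude = 4, frequency = 3,
                      dwell_ms = 8000, seed = 25, blinks = 0)
  seg <- segment_waveform(ses$recording)
  centre <- stats::median(seg$fs$x_smooth, na.rm = TRUE)
  sides <- sign(seg$foveations$mean_x - centre)
  expect_true(any(sides > 0) && any(sides < 0))
})
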