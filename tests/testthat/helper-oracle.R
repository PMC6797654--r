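# Independent brute-force oracle for foveation detection: naive loops,
# mean() per window, no shared code with detect_foveations().
brute_force_foveations <- function(fs, cycles, config = pipeline_config()) {
  rate <- sample_rate(fs)
  eligible <- fs$phase == "slow" & fs$valid & is.finite(fs$speed)
  n <- nrow(fs)
  out <- list()
  claimed <- 0L
  for (ci in which(cycles$complete)) {
    cyc <- cycles[ci, ]
    idx <- cyc$start:(cyc$end - 1L)
    n_slow <- sum(eligible[idx])
    if (n_slow == 0) next
    L <- max(1L, round(config$foveation_fraction * n_slow))
    if (L * 1000 / rate < config$min_foveation_ms) next
    best_s <- NA_integer_
    best_m <- Inf
    s_lo <- max(cyc$start, claimed + 1L)
    s_hi <- min(cyc$end, n - L + 1L)
    if (s_hi < s_lo) next
    for (s in s_lo:s_hi) {
      w <- s:(s + L - 1L)
      if (!all(eligible[w])) next  # contiguous eligible = one slow run
      m <- mean(fs$speed[w])
      if (m < best_m) {
        best_m <- m
        best_s <- s
      }
    }
    if (is.na(best_s)) next
    out[[length(out) + 1L]] <- data.frame(cycle_id = cyc$cycle_id,
                                          start = best_s,
                                          end = best_s + L)
    if (best_s + L - 1L >= cyc$end) claimed <- best_s + L - 1L
  }
  do.call(rbind, out)
}

# A short single-target jerk recording with ground truth.
sim_fixation <- function(kind = "jerk", amplitude = 4, frequency = 3,
                         dwell_ms = 5000, seed = 1, blinks = 0,
                         target_x = 0, target_y = 0, ...) {
  m <- five_point_manifest(dwell_ms = dwell_ms)[1, ]
  m$target_x_deg <- target_x
  m$target_y_deg <- target_y
  simulate_session(
    waveform_spec(kind, amplitude_deg = amplitude,
                  frequency_hz = frequency, ...),
    manifest = m, seed = seed, blinks_per_target = blinks
  )
}

# Recording holding an exact cubic polynomial on both axes.
cubic_recording <- function(n = 200, valid = rep(TRUE, n)) {
  t <- seq_len(n) - 1
  gaze_recording(t, 1e-6 * t^3 - 2e-4 * t^2 + 0.05 * t + 3,
                 -5e-7 * t^3 + 1e-4 * t^2 - 0.02 * t + 1,
                 valid = valid)
}

# Exact PORs of the five-point grid under an affine+rotation raw map.
affine_por <- function(theta_deg = 0, gx = 30, gy = 25, bx = 1000,
                       by = 800) {
  tr <- raw_transform(gain_x = gx, gain_y = gy, offset_x = bx,
                      offset_y = by, theta_deg = theta_deg)
  m <- five_point_manifest()
  raw <- tr$apply(cbind(m$target_x_deg, m$target_y_deg))
  tibble::tibble(target_id = m$target_id, x_raw = raw[, 1],
                 y_raw = raw[, 2], target_x_deg = m$target_x_deg,
                 target_y_deg = m$target_y_deg)
}

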