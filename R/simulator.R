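#' Specify a synthetic nystagmus waveform
#'
#' Defines one of three idealised infantile-nystagmus waveforms:
#' * `jerk` — an accelerating (exponential) slow phase drifting away from
#'   the fixation position, returned by a minimum-jerk quick phase;
#' * `jerk_extended_foveation` — as `jerk`, with a stationary plateau at
#'   the fixation position prepended to each slow phase;
#' * `pendular` — a pure sine about the fixation position.
#'
#' The slow-phase time constant defaults to half the slow-phase duration,
#' giving a clearly accelerating drift whose speed rises about threefold
#' over the phase.
#'
#' @param kind waveform type.
#' @param amplitude_deg peak-to-trough amplitude in degrees.
#' @param frequency_hz cycle frequency (0.5-10 Hz).
#' @param quick_phase_ms quick-phase duration (jerk kinds).
#' @param slow_phase_tau exponential time constant in seconds; `NULL` for
#'   half the slow-phase duration.
#' @param extended_foveation_ms plateau duration for
#'   `jerk_extended_foveation`.
#' @param direction `"right-beating"` (slow drift leftward, quick phase
#'   rightward) or `"left-beating"`.
#' @param vertical_noise_sd_deg SD of the vertical position about the
#'   fixation point (the simulated oscillation is horizontal).
#' @return list of class `waveform_spec`.
#' @export
waveform_spec <- function(kind = c("jerk", "jerk_extended_foveation",
                                   "pendular"),
                          amplitude_deg = 4,
                          frequency_hz = 3,
                          quick_phase_ms = 30,
                          slow_phase_tau = NULL,
                          extended_foveation_ms = 50,
                          direction = c("right-beating", "left-beating"),
                          vertical_noise_sd_deg = 0.05) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  stopifnot(amplitude_deg > 0, frequency_hz >= 0.5, frequency_hz <= 10)
  period_ms <- 1000 / frequency_hz
  if (kind != "pendular" && quick_phase_ms >= period_ms) {
    stop("quick phase must be shorter than the cycle period")
  }
  slow_ms <- period_ms - if (kind == "pendular") 0 else quick_phase_ms
  if (kind == "jerk_extended_foveation" && extended_foveation_ms >= slow_ms) {
    stop("extended foveation plateau must be shorter than the slow phase")
  }
  drift_ms <- slow_ms - if (kind == "jerk_extended_foveation") {
    extended_foveation_ms
  } else 0
  if (is.null(slow_phase_tau)) slow_phase_tau <- drift_ms / 2000
  if (kind != "pendular" && slow_phase_tau <= 0) {
    stop("non-monotone slow phase: tau must be positive")
  }
  structure(list(kind = kind, amplitude_deg = amplitude_deg,
                 frequency_hz = frequency_hz,
                 quick_phase_ms = if (kind == "pendular") 0 else quick_phase_ms,
                 slow_phase_tau = slow_phase_tau,
                 extended_foveation_ms = extended_foveation_ms,
                 direction = direction,
                 vertical_noise_sd_deg = vertical_noise_sd_deg,
                 period_ms = period_ms, slow_ms = slow_ms,
                 drift_ms = drift_ms),
            class = "waveform_spec")
}

# Noiseless horizontal position and velocity (deg, deg/s) at cycle-local
# times t_ms in [0, period_ms), fixation at 0.
waveform_cycle_true <- function(spec, t_ms) {
  A <- spec$amplitude_deg
  s <- if (spec$direction == "right-beating") -1 else 1
  if (spec$kind == "pendular") {
    f <- spec$frequency_hz
    return(list(x = A / 2 * sin(2 * pi * f * t_ms / 1000),
                v = A / 2 * 2 * pi * f * cos(2 * pi * f * t_ms / 1000),
                phase = rep("slow", length(t_ms))))
  }
  plateau <- if (spec$kind == "jerk_extended_foveation") {
    spec$extended_foveation_ms
  } else 0
  tau_ms <- spec$slow_phase_tau * 1000
  Td <- spec$drift_ms
  Tq <- spec$quick_phase_ms
  x <- numeric(length(t_ms))
  v <- numeric(length(t_ms))
  phase <- rep("slow", length(t_ms))
  denom <- expm1(Td / tau_ms)
  in_plateau <- t_ms < plateau
  in_drift <- t_ms >= plateau & t_ms < spec$slow_ms
  in_quick <- t_ms >= spec$slow_ms
  td <- t_ms[in_drift] - plateau
  x[in_drift] <- s * A * expm1(td / tau_ms) / denom
  v[in_drift] <- s * A * exp(td / tau_ms) / (tau_ms * denom) * 1000
  u <- (t_ms[in_quick] - spec$slow_ms) / Tq
  x[in_quick] <- s * A * (1 - (10 * u^3 - 15 * u^4 + 6 * u^5))
  v[in_quick] <- -s * A * (30 * u^2 - 60 * u^3 + 30 * u^4) / Tq * 1000
  phase[in_quick] <- "quick"
  list(x = x, v = v, phase = phase, in_plateau = in_plateau)
}

#' Simulate one waveform cycle
#'
#' Generates the noiseless samples of a single cycle at fixation 0 deg,
#' with ground-truth phase labels, analytic velocity, and the true
#' foveation window (the lowest-mean-true-speed window of one tenth of
#' the slow-phase duration, found by exhaustive search).
#'
#' @param spec a [waveform_spec()].
#' @param rate sampling rate in Hz.
#' @param foveation_fraction window length as a fraction of the
#'   slow-phase duration.
#' @return list with `samples` (tibble `t_ms`, `x_deg`, `v_deg_s`,
#'   `phase`) and `true_foveation` (start/end sample indices, half-open).
#' @export
simulate_cycle <- function(spec, rate = 1000, foveation_fraction = 0.10) {
  t_ms <- seq(0, spec$period_ms - 1000 / rate, by = 1000 / rate)
  w <- waveform_cycle_true(spec, t_ms)
  slow <- w$phase == "slow"
  L <- max(1L, as.integer(round(foveation_fraction * sum(slow))))
  spd <- abs(w$v)
  starts <- which(slow)
  starts <- starts[starts + L - 1L <= length(t_ms)]
  starts <- starts[vapply(starts, function(s) all(slow[s:(s + L - 1L)]),
                          logical(1))]
  means <- vapply(starts, function(s) mean(spd[s:(s + L - 1L)]), numeric(1))
  best <- starts[which.min(means)]
  list(
    samples = tibble::tibble(t_ms = t_ms, x_deg = w$x, v_deg_s = w$v,
                             phase = w$phase),
    true_foveation = c(start = best, end = best + L)
  )
}

#' Raw-unit transform of a simulated session
#'
#' The unknown mapping from true gaze degrees to tracker units:
#' `raw = diag(gain) %*% R(theta) %*% deg + offset`, i.e. a rotation of
#' the calibration field (head tilt) followed by independent per-axis
#' gains and offsets. Invertible as an affine map; the `linear_xtalk`
#' calibration model recovers its inverse exactly.
#'
#' @param gain_x,gain_y axis gains in units/deg (nonzero).
#' @param offset_x,offset_y axis offsets in raw units.
#' @param theta_deg field rotation in degrees.
#' @return list of class `raw_transform` with `apply` and `invert`
#'   functions taking an n-by-2 matrix.
#' @export
raw_transform <- function(gain_x = 30, gain_y = 25,
                          offset_x = 1000, offset_y = 800,
                          theta_deg = 0) {
  stopifnot(gain_x != 0, gain_y != 0)
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  G <- diag(c(gain_x, gain_y))
  M <- G %*% R
  Minv <- solve(M)
  b <- c(offset_x, offset_y)
  structure(list(
    gain_x = gain_x, gain_y = gain_y,
    offset_x = offset_x, offset_y = offset_y, theta_deg = theta_deg,
    apply = function(deg) sweep(deg %*% t(M), 2, b, "+"),
    invert = function(raw) sweep(raw, 2, b, "-") %*% t(Minv)
  ), class = "raw_transform")
}

#' Simulate an uncalibrated calibration session
#'
#' Generates a full seeded recording of the calibration protocol: for
#' each manifest target, the specified waveform oscillates about the
#' target position for the target's display interval; true gaze in
#' degrees passes through additive white Gaussian noise and the raw
#' transform to produce tracker units; blinks are inserted as invalid
#' runs with brief position spikes on both edges (as real lid closures
#' produce). Fully reproducible for a fixed seed.
#'
#' @param spec a [waveform_spec()] (or list of one per target).
#' @param manifest target manifest (see [five_point_manifest()]).
#' @param transform a [raw_transform()].
#' @param seed integer RNG seed.
#' @param rate sampling rate in Hz.
#' @param noise_sd_deg SD of additive position noise, in degrees.
#' @param blinks_per_target number of blinks inserted per target.
#' @param blink_duration_ms blink (invalid-run) duration.
#' @param blink_spike_ms duration of the position spike flanking each
#'   blink.
#' @return list with `recording` (raw-unit tibble), `truth` (per-sample
#'   tibble `t_ms`, `x_deg_true`, `y_deg_true`, `speed_true`,
#'   `phase_true`, `target_id`), `true_foveations`,
#'   `true_quick_phases`, `cycle_boundaries_ms` (tibbles/vector),
#'   `transform`, `manifest`, and `fixations_raw` (true fixation
#'   position per target in raw units).
#' @export
simulate_session <- function(spec,
                             manifest = five_point_manifest(),
                             transform = raw_transform(),
                             seed = 1,
                             rate = 1000,
                             noise_sd_deg = 0.05,
                             blinks_per_target = 1,
                             blink_duration_ms = 150,
                             blink_spike_ms = 20) {
  set.seed(seed)
  validate_manifest(manifest)
  specs <- if (inherits(spec, "waveform_spec")) {
    rep(list(spec), nrow(manifest))
  } else spec
  stopifnot(length(specs) == nrow(manifest))
  dt <- 1000 / rate

  per_target <- lapply(seq_len(nrow(manifest)), function(i) {
    tg <- manifest[i, ]
    sp <- specs[[i]]
    t_rel <- seq(0, tg$end_ms - tg$start_ms - dt, by = dt)
    cyc <- t_rel %% sp$period_ms
    cyc_id <- floor(t_rel / sp$period_ms)
    w <- waveform_cycle_true(sp, cyc)
    tibble::tibble(
      t_ms = tg$start_ms + t_rel,
      x_deg_true = tg$target_x_deg + w$x,
      y_deg_true = tg$target_y_deg,
      v_true = w$v,
      phase_true = w$phase,
      target_id = tg$target_id,
      local_cycle = cyc_id
    )
  })
  truth <- dplyr::bind_rows(per_target)
  n <- nrow(truth)

  # true per-cycle foveations and quick phases, by exhaustive search on
  # the analytic speed
  spd_true <- abs(truth$v_true)
  true_fov <- list(); true_qp <- list(); boundaries <- numeric(0)
  for (i in seq_len(nrow(manifest))) {
    sp <- specs[[i]]
    seg <- which(truth$target_id == manifest$target_id[i])
    fov1 <- simulate_cycle(sp, rate)$true_foveation
    for (k in unique(truth$local_cycle[seg])) {
      idx <- seg[truth$local_cycle[seg] == k]
      if (length(idx) < round(sp$period_ms / dt)) next  # truncated cycle
      true_fov[[length(true_fov) + 1L]] <- tibble::tibble(
        target_id = manifest$target_id[i],
        start = idx[1] + fov1[["start"]] - 1L,
        end = idx[1] + fov1[["end"]] - 1L
      )
      qp <- idx[truth$phase_true[idx] == "quick"]
      if (length(qp) > 0) {
        true_qp[[length(true_qp) + 1L]] <- tibble::tibble(
          target_id = manifest$target_id[i],
          start = qp[1], end = qp[length(qp)] + 1L
        )
      }
      # cycle boundary at the slow-phase end (waveform extremum)
      boundaries <- c(boundaries,
                      truth$t_ms[idx[1]] + sp$slow_ms)
    }
  }

  # observed = truth + noise, in degrees, then mapped to raw units
  x_obs <- truth$x_deg_true + stats::rnorm(n, 0, noise_sd_deg)
  y_obs <- truth$y_deg_true + stats::rnorm(n, 0, noise_sd_deg) +
    stats::rnorm(n, 0, specs[[1]]$vertical_noise_sd_deg)
  valid <- rep(TRUE, n)

  # blinks: invalid runs with position spikes on both edges
  spike_n <- max(1L, round(blink_spike_ms / dt))
  blink_n <- max(1L, round(blink_duration_ms / dt))
  if (blinks_per_target > 0) {
    for (i in seq_len(nrow(manifest))) {
      seg <- which(truth$target_id == manifest$target_id[i])
      for (b in seq_len(blinks_per_target)) {
        margin <- 2L * (spike_n + blink_n)
        lo <- seg[1] + margin
        hi <- seg[length(seg)] - margin - blink_n
        if (hi <= lo) next                 # segment too short for a blink
        s <- sample(lo:hi, 1)
        gap <- s:(s + blink_n - 1L)
        valid[gap] <- FALSE
        pre <- (s - spike_n):(s - 1L)
        post <- (s + blink_n):(s + blink_n + spike_n - 1L)
        spike <- 5 * specs[[i]]$amplitude_deg
        x_obs[pre] <- x_obs[pre] + spike * seq(0, 1, length.out = spike_n)
        x_obs[post] <- x_obs[post] + spike * seq(1, 0, length.out = spike_n)
        y_obs[pre] <- y_obs[pre] - spike * seq(0, 1, length.out = spike_n)
        y_obs[post] <- y_obs[post] - spike * seq(1, 0, length.out = spike_n)
      }
    }
  }

  raw <- transform$apply(cbind(x_obs, y_obs))
  rec <- gaze_recording(truth$t_ms,
                        ifelse(valid, raw[, 1], NA_real_),
                        ifelse(valid, raw[, 2], NA_real_),
                        valid = valid)
  fix_raw <- transform$apply(cbind(manifest$target_x_deg,
                                   manifest$target_y_deg))
  list(
    recording = rec,
    truth = tibble::tibble(t_ms = truth$t_ms,
                           x_deg_true = truth$x_deg_true,
                           y_deg_true = truth$y_deg_true,
                           speed_true = spd_true,
                           phase_true = truth$phase_true,
                           target_id = truth$target_id),
    true_foveations = dplyr::bind_rows(true_fov),
    true_quick_phases = dplyr::bind_rows(true_qp),
    cycle_boundaries_ms = boundaries,
    transform = transform,
    manifest = manifest,
    fixations_raw = tibble::tibble(target_id = manifest$target_id,
                                   x_raw = fix_raw[, 1],
                                   y_raw = fix_raw[, 2])
  )
}
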