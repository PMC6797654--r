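#' Classic fixed-threshold foveation detection
#'
#' The traditional, calibration-dependent criterion: maximal runs of
#' valid samples whose speed stays below a fixed threshold (classically
#' 4 deg/s) for at least a minimum duration (classically 7 ms). When a
#' position window is given, runs whose mean primary-axis position
#' deviates from the median of all run means by more than the window are
#' rejected (successive foveations must lie close to one another).
#'
#' @param cal calibrated tibble from [apply_calibration()] with a
#'   `speed_deg_s` column.
#' @param v_thresh speed threshold, deg/s.
#' @param min_dur_ms minimum run duration, ms.
#' @param pos_window_deg positional constraint in degrees, or `NULL` to
#'   disable.
#' @return tibble with one row per foveation run: `start`, `end`
#'   (half-open indices), `duration_ms`, `mean_x_deg`, `mean_y_deg`,
#'   `mean_speed_deg_s`.
#' @export
classic_foveation_detect <- function(cal, v_thresh = 4, min_dur_ms = 7,
                                     pos_window_deg = NULL) {
  stopifnot("speed_deg_s" %in% names(cal))
  rate <- sample_rate(cal)
  below <- cal$valid & is.finite(cal$speed_deg_s) &
    cal$speed_deg_s < v_thresh
  runs <- mask_runs(below)
  if (nrow(runs) == 0) return(empty_classic_runs())
  runs$duration_ms <- (runs$end - runs$start + 1L) * 1000 / rate
  runs <- runs[runs$duration_ms >= min_dur_ms, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_classic_runs())
  vertical <- identical(cal$axis[1], "vertical")
  pos <- if (vertical) cal$y_deg else cal$x_deg
  out <- tibble::tibble(
    start = runs$start,
    end = runs$end + 1L,
    duration_ms = runs$duration_ms,
    mean_x_deg = vapply(seq_len(nrow(runs)), function(i) {
      mean(cal$x_deg[runs$start[i]:runs$end[i]])
    }, numeric(1)),
    mean_y_deg = vapply(seq_len(nrow(runs)), function(i) {
      mean(cal$y_deg[runs$start[i]:runs$end[i]])
    }, numeric(1)),
    mean_speed_deg_s = vapply(seq_len(nrow(runs)), function(i) {
      mean(cal$speed_deg_s[runs$start[i]:runs$end[i]])
    }, numeric(1))
  )
  if (!is.null(pos_window_deg) && is.finite(pos_window_deg)) {
    mp <- if (vertical) out$mean_y_deg else out$mean_x_deg
    out <- out[abs(mp - stats::median(mp)) <= pos_window_deg, ,
               drop = FALSE]
  }
  out
}

empty_classic_runs <- function() {
  tibble::tibble(start = integer(0), end = integer(0),
                 duration_ms = numeric(0), mean_x_deg = numeric(0),
                 mean_y_deg = numeric(0), mean_speed_deg_s = numeric(0))
}

#' Waveform metrics: amplitude, frequency, intensity
#'
#' Amplitude is the median over complete cycles of the peak-to-trough
#' primary-axis position range; frequency is the cycle count divided by
#' the spanned duration; nystagmus intensity is their product (deg/s for
#' calibrated input).
#'
#' @param sig calibrated tibble (uses `x_deg`/`y_deg`) or filtered signal
#'   (uses smoothed raw positions).
#' @param cycles cycle tibble from [split_cycles()].
#' @return one-row tibble: `amplitude`, `frequency_hz`, `intensity`,
#'   `n_cycles`.
#' @export
nystagmus_metrics <- function(sig, cycles) {
  if (nrow(cycles) == 0) stop("no cycles: cannot compute waveform metrics")
  vertical <- identical(sig$axis[1], "vertical")
  pos <- if ("x_deg" %in% names(sig)) {
    if (vertical) sig$y_deg else sig$x_deg
  } else {
    if (vertical) sig$y_smooth else sig$x_smooth
  }
  use <- if (any(cycles$complete)) cycles[cycles$complete, ] else cycles
  amp <- stats::median(vapply(seq_len(nrow(use)), function(i) {
    idx <- use$start[i]:use$end[i]
    diff(range(pos[idx], na.rm = TRUE))
  }, numeric(1)))
  span_s <- (sig$t_ms[cycles$end[nrow(cycles)]] -
               sig$t_ms[cycles$start[1]]) / 1000
  freq <- nrow(cycles) / span_s
  tibble::tibble(amplitude = amp, frequency_hz = freq,
                 intensity = amp * freq, n_cycles = nrow(cycles))
}

#' Nonselective point of regard (control method)
#'
#' The control against which foveation-based calibration is compared:
#' the per-coordinate median of every valid sample in the target
#' interval, quick phases included, with no segmentation at all.
#'
#' @param rec recording tibble (raw positions are used).
#' @param target one-row manifest entry.
#' @param skip_initial_ms leading portion of the interval to skip.
#' @return one-row tibble shaped like [point_of_regard()] output.
#' @export
nonselective_por <- function(rec, target, skip_initial_ms = 300) {
  t0 <- target$start_ms + skip_initial_ms
  idx <- which(rec$t_ms >= t0 & rec$t_ms < target$end_ms & rec$valid)
  if (length(idx) == 0) stop("no valid samples in target interval")
  tibble::tibble(
    target_id = target$target_id,
    x_raw = stats::median(rec$x[idx]),
    y_raw = stats::median(rec$y[idx]),
    n_foveations = NA_integer_,
    n_samples = length(idx),
    target_x_deg = target$target_x_deg,
    target_y_deg = target$target_y_deg
  )
}

#' Compare POR methods against a reference
#'
#' Expresses, per target, the Euclidean error of the algorithmic and
#' nonselective points of regard relative to a reference POR (expert
#' marking or simulator ground truth), in calibrated degrees and as a
#' percentage of the median nystagmus amplitude. The difference column is
#' nonselective minus algorithmic: positive values mean the foveation-
#' based method was closer to the reference.
#'
#' @param algorithmic,nonselective,reference POR tibbles in the same raw
#'   frame (columns `target_id`, `x_raw`, `y_raw`).
#' @param model a fitted `nyst_calibration` used to express errors in
#'   degrees.
#' @param amplitude_deg median nystagmus amplitude (deg) for the
#'   percentage normalisation.
#' @return tibble with one row per target: errors in deg and % of
#'   amplitude per method, plus their difference.
#' @export
compare_methods <- function(algorithmic, nonselective, reference, model,
                            amplitude_deg) {
  stopifnot(nrow(reference) >= 1)
  to_deg <- function(por) {
    X <- cal_design(por$x_raw, por$y_raw, model$order)
    tibble::tibble(target_id = por$target_id,
                   x_deg = drop(X %*% model$coef$x),
                   y_deg = drop(X %*% model$coef$y))
  }
  a <- to_deg(algorithmic); ns <- to_deg(nonselective); rf <- to_deg(reference)
  j <- dplyr::inner_join(
    dplyr::inner_join(a, ns, by = "target_id", suffix = c("_alg", "_non")),
    rf, by = "target_id"
  )
  err <- function(x1, y1) sqrt((x1 - j$x_deg)^2 + (y1 - j$y_deg)^2)
  out <- tibble::tibble(
    target_id = j$target_id,
    nonselective_deg = err(j$x_deg_non, j$y_deg_non),
    algorithmic_deg = err(j$x_deg_alg, j$y_deg_alg)
  )
  out$difference_deg <- out$nonselective_deg - out$algorithmic_deg
  out$nonselective_pct <- 100 * out$nonselective_deg / amplitude_deg
  out$algorithmic_pct <- 100 * out$algorithmic_deg / amplitude_deg
  out$difference_pct <- out$nonselective_pct - out$algorithmic_pct
  out
}
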