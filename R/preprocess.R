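# Run-length utilities shared across modules: maximal runs of a logical
# mask, as (start, end) sample indices (inclusive).
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Interpolate short tracking gaps
#'
#' Invalid runs spanning at most `max_gap_ms` are replaced by cubic-spline
#' values fitted on the flanking valid samples and marked valid. Longer
#' runs, and runs touching either end of the recording, are left
#' untouched. Valid samples are never altered, so the operation is
#' idempotent.
#'
#' @param rec recording tibble.
#' @param max_gap_ms longest repairable gap, in ms.
#' @param flank number of valid samples on each side used to fit the
#'   spline.
#' @return recording tibble of identical length and timestamps.
#' @export
interpolate_gaps <- function(rec, max_gap_ms = 25, flank = 8L) {
  stopifnot(max_gap_ms > 0)
  rate <- sample_rate(rec)
  gaps <- mask_runs(!rec$valid)
  if (nrow(gaps) == 0) return(rec)
  n <- nrow(rec)
  for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; e <- gaps$end[i]
    if (s == 1L || e == n) next                    # boundary gap: no flank
    if ((e - s + 1L) * 1000 / rate > max_gap_ms) next
    left <- which(rec$valid[seq_len(s - 1L)])
    right <- which(rec$valid[(e + 1L):n]) + e
    left <- utils::tail(left, flank)
    right <- utils::head(right, flank)
    if (length(left) < 2L || length(right) < 2L) next
    anchors <- c(left, right)
    idx <- s:e
    rec$x[idx] <- stats::splinefun(rec$t_ms[anchors], rec$x[anchors],
                                   method = "fmm")(rec$t_ms[idx])
    rec$y[idx] <- stats::splinefun(rec$t_ms[anchors], rec$y[anchors],
                                   method = "fmm")(rec$t_ms[idx])
    rec$valid[idx] <- TRUE
  }
  rec
}

#' Trim blink margins around remaining gaps
#'
#' Blinks corrupt eye position before the tracker loses the pupil and
#' after it reacquires it. Every sample within `pad_ms` before the first
#' and after the last sample of each remaining gap is invalidated;
#' overlapping pads merge and pads are clipped at the recording
#' boundaries. Gaps are the runs with missing positions; padded samples
#' keep their position values (only `valid` is cleared), so applying the
#' operation twice changes nothing.
#'
#' @param rec recording tibble (after [interpolate_gaps()]).
#' @param pad_ms margin trimmed on either side of each gap, in ms.
#' @return recording tibble of identical length and timestamps.
#' @export
trim_blinks <- function(rec, pad_ms = 75) {
  stopifnot(pad_ms > 0)
  gaps <- mask_runs(!rec$valid & (is.na(rec$x) | is.na(rec$y)))
  if (nrow(gaps) == 0) return(rec)
  drop <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(gaps))) {
    t0 <- rec$t_ms[gaps$start[i]] - pad_ms
    t1 <- rec$t_ms[gaps$end[i]] + pad_ms
    drop <- drop | (rec$t_ms >= t0 & rec$t_ms <= t1)
  }
  rec$valid[drop] <- FALSE
  rec
}

#' Smooth the gaze signal and estimate eye speed
#'
#' Each axis is smoothed and differentiated with a Savitzky-Golay (local
#' least-squares polynomial) filter, applied independently to every
#' maximal valid segment so that blink artifacts never leak across gaps.
#' Velocities are scaled by the sampling rate to arbitrary units per
#' second. Segments shorter than the filter window are passed through
#' unsmoothed with their speed masked.
#'
#' The detection `speed` column is, by default, the absolute velocity of
#' the primary nystagmus axis (the axis with the larger position standard
#' deviation): the two raw axes have different unknown gains, so mixing
#' them is not meaningful. `speed_mode = "magnitude"` instead combines the
#' axes after dividing each velocity by its median absolute deviation.
#'
#' @param rec cleaned recording tibble.
#' @param config a [pipeline_config()].
#' @param axis `"auto"` (primary axis by position SD), `"horizontal"` or
#'   `"vertical"`.
#' @return tibble with columns `t_ms`, `x`, `y`, `valid`, `x_smooth`,
#'   `y_smooth`, `vel_x`, `vel_y`, `speed`, `axis`.
#' @export
filter_gaze <- function(rec, config = pipeline_config(),
                        axis = c("auto", "horizontal", "vertical")) {
  axis <- match.arg(axis)
  rate <- sample_rate(rec)
  w <- sg_window_for_rate(config, rate)
  fs <- rec
  fs$x_smooth <- NA_real_
  fs$y_smooth <- NA_real_
  fs$vel_x <- NA_real_
  fs$vel_y <- NA_real_
  segs <- mask_runs(rec$valid)
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    if (length(idx) < w) {       # too short to filter: pass through, mask speed
      fs$x_smooth[idx] <- rec$x[idx]
      fs$y_smooth[idx] <- rec$y[idx]
      next
    }
    fs$x_smooth[idx] <- signal::sgolayfilt(rec$x[idx], p = config$sg_order,
                                           n = w, m = 0)
    fs$y_smooth[idx] <- signal::sgolayfilt(rec$y[idx], p = config$sg_order,
                                           n = w, m = 0)
    fs$vel_x[idx] <- signal::sgolayfilt(rec$x[idx], p = config$sg_order,
                                        n = w, m = 1) * rate
    fs$vel_y[idx] <- signal::sgolayfilt(rec$y[idx], p = config$sg_order,
                                        n = w, m = 1) * rate
  }
  if (axis == "auto") {
    axis <- primary_axis(fs)
  }
  fs$axis <- axis
  if (config$speed_mode == "primary") {
    fs$speed <- abs(if (axis == "horizontal") fs$vel_x else fs$vel_y)
  } else {
    mx <- stats::mad(fs$vel_x, na.rm = TRUE)
    my <- stats::mad(fs$vel_y, na.rm = TRUE)
    mx <- if (mx > 0) mx else 1
    my <- if (my > 0) my else 1
    fs$speed <- sqrt((fs$vel_x / mx)^2 + (fs$vel_y / my)^2)
  }
  fs
}
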