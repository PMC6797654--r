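#' Pipeline configuration
#'
#' Bundles every tunable constant of the segmentation and calibration
#' pipeline. Defaults reproduce the published protocol: gaps of at most
#' 25 ms are spline-interpolated, 75 ms is trimmed on either side of
#' remaining gaps, the foveation window is 10% of the slow-phase duration
#' within a cycle with a 7 ms floor, data capture below 85% raises a
#' warning, and the classic (post-calibration) foveation criterion is
#' speed below 4 deg/s with an optional +/- 0.5 deg position window.
#'
#' @param max_gap_ms longest invalid run (ms) repaired by cubic-spline
#'   interpolation.
#' @param blink_pad_ms margin (ms) invalidated on either side of any gap
#'   remaining after interpolation.
#' @param foveation_fraction fraction of a cycle's total slow-phase
#'   duration used as the foveation window length.
#' @param min_foveation_ms foveation windows shorter than this are
#'   disregarded.
#' @param capture_threshold minimum fraction of valid samples for a
#'   recording to pass the data-quality check.
#' @param skip_initial_ms leading portion of each target interval excluded
#'   from analysis (time to take up fixation).
#' @param classic_velocity_thresh_deg_s fixed speed threshold (deg/s) for
#'   classic foveation detection on calibrated data.
#' @param classic_position_window_deg positional constraint (deg) for
#'   classic foveation detection; `NA` disables it.
#' @param sg_order,sg_window_1000hz Savitzky-Golay polynomial order and
#'   window length (samples) at 1000 Hz; the window is rescaled (kept odd)
#'   for other sampling rates.
#' @param speed_mode `"primary"` uses the primary-axis speed for detection;
#'   `"magnitude"` combines both axes after dividing each by its median
#'   absolute deviation (the axes have incommensurate raw gains).
#' @param saccade_k multiplier on the MAD of speed above the median speed
#'   for quick-phase candidacy.
#' @param min_saccade_ms quick-phase runs shorter than this are discarded.
#' @param merge_ms quick-phase runs separated by less than this merge.
#' @param peak_prominence_frac minimum peak prominence as a fraction of the
#'   IQR of the primary-axis position.
#' @param peak_polarity `"auto"` picks the polarity (peaks vs troughs)
#'   whose extrema sit at lower local speed; `"peaks"`/`"troughs"` force it.
#' @param min_rate_hz sampling rates below this are rejected.
#'
#' @return A list of class `nyst_config`.
#' @export
pipeline_config <- function(max_gap_ms = 25,
                            blink_pad_ms = 75,
                            foveation_fraction = 0.10,
                            min_foveation_ms = 7,
                            capture_threshold = 0.85,
                            skip_initial_ms = 300,
                            classic_velocity_thresh_deg_s = 4,
                            classic_position_window_deg = 0.5,
                            sg_order = 3,
                            sg_window_1000hz = 21,
                            speed_mode = c("primary", "magnitude"),
                            saccade_k = 6,
                            min_saccade_ms = 10,
                            merge_ms = 10,
                            peak_prominence_frac = 0.2,
                            peak_polarity = c("auto", "peaks", "troughs"),
                            min_rate_hz = 200) {
  speed_mode <- match.arg(speed_mode)
  peak_polarity <- match.arg(peak_polarity)
  stopifnot(
    max_gap_ms > 0, blink_pad_ms > 0, min_foveation_ms > 0,
    min_saccade_ms > 0, merge_ms > 0, skip_initial_ms >= 0,
    foveation_fraction > 0, foveation_fraction < 1,
    capture_threshold > 0, capture_threshold <= 1,
    sg_order >= 1, sg_window_1000hz > sg_order,
    saccade_k > 0, peak_prominence_frac > 0, min_rate_hz > 0
  )
  structure(list(
    max_gap_ms = max_gap_ms,
    blink_pad_ms = blink_pad_ms,
    foveation_fraction = foveation_fraction,
    min_foveation_ms = min_foveation_ms,
    capture_threshold = capture_threshold,
    skip_initial_ms = skip_initial_ms,
    classic_velocity_thresh_deg_s = classic_velocity_thresh_deg_s,
    classic_position_window_deg = classic_position_window_deg,
    sg_order = sg_order,
    sg_window_1000hz = sg_window_1000hz,
    speed_mode = speed_mode,
    saccade_k = saccade_k,
    min_saccade_ms = min_saccade_ms,
    merge_ms = merge_ms,
    peak_prominence_frac = peak_prominence_frac,
    peak_polarity = peak_polarity,
    min_rate_hz = min_rate_hz
  ), class = "nyst_config")
}

#' Savitzky-Golay window length for a sampling rate
#'
#' Scales the 1000 Hz default window to `rate` and forces it odd and
#' larger than the polynomial order.
#' @param config a [pipeline_config()].
#' @param rate sampling rate in Hz.
#' @return odd integer window length in samples.
#' @keywords internal
sg_window_for_rate <- function(config, rate) {
  w <- round(config$sg_window_1000hz * rate / 1000)
  if (w %% 2 == 0) w <- w + 1
  wmin <- config$sg_order + 1 + (config$sg_order %% 2) # smallest odd > order
  max(w, wmin)
}
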