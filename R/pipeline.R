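#' Run the full segmentation pipeline on a raw recording
#'
#' Convenience wrapper chaining gap interpolation, blink trimming,
#' filtering/differentiation, cycle splitting, quick-phase detection and
#' foveation detection. Returns every intermediate product plus a run
#' log with one record per stage, so silent mis-segmentation shows up as
#' an implausible count.
#'
#' @param rec raw recording tibble.
#' @param config a [pipeline_config()].
#' @return list with `fs` (filtered signal with `phase`), `cycles`,
#'   `foveations`, `capture` (quality report) and `log` (stage tibble).
#' @export
segment_waveform <- function(rec, config = pipeline_config()) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, ...)
  }
  capture <- check_capture(rec, config$capture_threshold, warn = TRUE)
  note("capture", count = capture$n_valid,
       detail = sprintf("%.1f%% valid", 100 * capture$capture))

  n_invalid0 <- sum(!rec$valid)
  rec <- interpolate_gaps(rec, config$max_gap_ms)
  note("interpolate_gaps", count = n_invalid0 - sum(!rec$valid),
       detail = "samples filled")

  n_valid0 <- sum(rec$valid)
  rec <- trim_blinks(rec, config$blink_pad_ms)
  note("trim_blinks", count = n_valid0 - sum(rec$valid),
       detail = "samples trimmed")

  fs <- filter_gaze(rec, config)
  note("filter", count = nrow(fs), detail = paste("axis", fs$axis[1]))

  cycles <- split_cycles(fs, config)
  note("split_cycles", count = nrow(cycles),
       detail = sprintf("%d complete", sum(cycles$complete)))

  fs <- detect_quick_phases(fs, config)
  note("quick_phases", count = sum(fs$phase == "quick"),
       detail = "quick-labeled samples")

  foveations <- detect_foveations(fs, cycles, config)
  note("foveations", count = nrow(foveations), detail = "windows")

  list(fs = fs, cycles = cycles, foveations = foveations,
       capture = capture, log = dplyr::bind_rows(log))
}

#' Calibrate an eye tracker from a nystagmus recording
#'
#' End-to-end calibration: segments the recording, computes the
#' foveation-based point of regard for every manifest target, and fits
#' the raw-to-degrees model.
#'
#' @param rec raw recording tibble.
#' @param manifest target manifest (see [five_point_manifest()]).
#' @param config a [pipeline_config()].
#' @param order calibration model order (see [fit_calibration()]).
#' @return list with `model` (`nyst_calibration`), `por`, and the
#'   [segment_waveform()] products.
#' @export
calibrate_session <- function(rec, manifest, config = pipeline_config(),
                              order = "linear_xtalk") {
  seg <- segment_waveform(rec, config)
  por <- por_table(seg$fs, seg$foveations, manifest,
                   skip_initial_ms = config$skip_initial_ms)
  model <- fit_calibration(por, order = order)
  c(list(model = model, por = por), seg)
}

#' Analyze a recording after calibration
#'
#' Applies a calibration, recomputes waveform metrics in degrees, and
#' runs the classic fixed-threshold foveation detector for comparison
#' with the adaptive method. The per-cycle mean speed of the adaptively
#' selected windows gives the foveation velocity threshold the waveform
#' actually supports.
#'
#' @param rec raw recording tibble.
#' @param model a fitted `nyst_calibration`.
#' @param config a [pipeline_config()].
#' @return list with `calibrated` (degrees tibble), `metrics`,
#'   `adaptive_foveations` (with `mean_speed_deg_s`), `classic_foveations`
#'   and `log`.
#' @export
analyze_recording <- function(rec, model, config = pipeline_config()) {
  seg <- segment_waveform(rec, config)
  cal <- apply_calibration(model, seg$fs)
  metrics <- if (nrow(seg$cycles) > 0) {
    nystagmus_metrics(cal, seg$cycles)
  } else {
    tibble::tibble(amplitude = NA_real_, frequency_hz = NA_real_,
                   intensity = NA_real_, n_cycles = 0L)
  }
  fov <- seg$foveations
  if (nrow(fov) > 0) {
    # adaptive windows re-expressed in deg/s through the calibration gain
    fov$mean_speed_deg_s <- vapply(seq_len(nrow(fov)), function(i) {
      mean(cal$speed_deg_s[fov$start[i]:(fov$end[i] - 1L)])
    }, numeric(1))
  }
  classic <- classic_foveation_detect(
    cal,
    v_thresh = config$classic_velocity_thresh_deg_s,
    min_dur_ms = config$min_foveation_ms,
    pos_window_deg = config$classic_position_window_deg
  )
  list(calibrated = cal, metrics = metrics, adaptive_foveations = fov,
       classic_foveations = classic, cycles = seg$cycles, log = seg$log)
}

#' Plot a segmented waveform
#'
#' Primary-axis position coloured by phase, with detected foveation
#' windows and cycle boundaries overlaid.
#'
#' @param seg result of [segment_waveform()].
#' @param t_range optional numeric length-2 time window (ms) to display.
#' @return a ggplot object.
#' @export
plot_segmentation <- function(seg, t_range = NULL) {
  fs <- seg$fs
  vertical <- identical(fs$axis[1], "vertical")
  fs$pos <- if (vertical) fs$y_smooth else fs$x_smooth
  if (!is.null(t_range)) {
    fs <- dplyr::filter(fs, .data$t_ms >= t_range[1],
                        .data$t_ms <= t_range[2])
  }
  fov <- seg$foveations
  fov <- fov[fov$start_ms >= min(fs$t_ms) & fov$end_ms <= max(fs$t_ms), ]
  bnd <- seg$fs$t_ms[seg$cycles$start]
  bnd <- bnd[bnd >= min(fs$t_ms) & bnd <= max(fs$t_ms)]
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$t_ms, y = .data$pos)) +
    ggplot2::geom_vline(xintercept = bnd, colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$phase, group = 1),
                       na.rm = TRUE) +
    ggplot2::geom_rect(
      data = fov, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.2
    ) +
    ggplot2::scale_colour_manual(values = c(
      slow = "steelblue", quick = "seagreen", invalid = "grey60"
    )) +
    ggplot2::labs(x = "time (ms)",
                  y = sprintf("%s position (arbitrary units)",
                              if (vertical) "vertical" else "horizontal"),
                  colour = "phase") +
    ggplot2::theme_minimal()
}
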