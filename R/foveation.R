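#' Foveation window length for a cycle
#'
#' The foveation window lasts a fixed fraction (default 10%) of the total
#' slow-phase duration within the cycle; a cycle may contain several slow
#' phases and their durations are summed. The length is rounded to whole
#' samples (at least 1). Cycles whose window would be shorter than
#' `min_foveation_ms` contribute no foveation.
#'
#' @param n_slow number of slow-labeled samples in the cycle.
#' @param rate sampling rate in Hz.
#' @param foveation_fraction fraction of the slow-phase duration.
#' @return window length in samples (integer, possibly 0-eligible; check
#'   against the duration floor separately).
#' @export
foveation_window_samples <- function(n_slow, rate,
                                     foveation_fraction = 0.10) {
  max(1L, as.integer(round(foveation_fraction * n_slow)))
}

#' Detect per-cycle foveation periods
#'
#' For each complete cycle, every candidate window of the cycle's
#' foveation length is scored by its mean eye speed (in arbitrary units
#' per second) and the window with the lowest mean speed wins; ties go to
#' the earliest start. A candidate window must consist entirely of
#' slow-labeled valid samples lying within a single slow run (a window
#' straddling a quick phase would average in saccadic speed), must start
#' no earlier than the cycle's opening peak, and may extend up to one
#' window length past the cycle's closing peak (foveations often sit at
#' the cycle boundary, especially in pendular waveforms). Samples claimed
#' past the boundary are unavailable to the next cycle, so no sample is
#' assigned to two foveations. Windows shorter than `min_foveation_ms`
#' are disregarded.
#'
#' @param fs filtered-signal tibble with a `phase` column
#'   (see [detect_quick_phases()]).
#' @param cycles cycle tibble; only rows with `complete = TRUE` are
#'   searched.
#' @param config a [pipeline_config()].
#' @return tibble with one row per detected foveation: `cycle_id`,
#'   `start`, `end` (half-open sample indices), `start_ms`, `end_ms`,
#'   `duration_ms`, `mean_x`, `mean_y`, `mean_speed`.
#' @export
detect_foveations <- function(fs, cycles, config = pipeline_config()) {
  rate <- sample_rate(fs)
  n <- nrow(fs)
  eligible <- fs$phase == "slow" & fs$valid & is.finite(fs$speed)
  # id of the maximal slow run each sample belongs to (NA outside runs)
  run_id <- rep(NA_integer_, n)
  runs <- mask_runs(eligible)
  for (i in seq_len(nrow(runs))) run_id[runs$start[i]:runs$end[i]] <- i
  cs <- c(0, cumsum(ifelse(is.finite(fs$speed), fs$speed, 0)))

  cycles <- cycles[cycles$complete, , drop = FALSE]
  out <- vector("list", nrow(cycles))
  claimed_until <- 0L   # first index still free after a spilled window
  for (ci in seq_len(nrow(cycles))) {
    cyc <- cycles[ci, ]
    in_cycle <- cyc$start:(cyc$end - 1L)
    n_slow <- sum(eligible[in_cycle])
    if (n_slow == 0L) next
    L <- foveation_window_samples(n_slow, rate, config$foveation_fraction)
    if (L * 1000 / rate < config$min_foveation_ms) next
    s_lo <- max(cyc$start, claimed_until + 1L)
    s_hi <- min(cyc$end, n - L + 1L)
    if (s_hi < s_lo) next
    starts <- s_lo:s_hi
    # window must sit inside one slow run
    starts <- starts[!is.na(run_id[starts]) &
                       !is.na(run_id[starts + L - 1L]) &
                       run_id[starts] == run_id[starts + L - 1L]]
    if (length(starts) == 0L) next
    mean_speed <- (cs[starts + L] - cs[starts]) / L
    best <- starts[which.min(mean_speed)]
    idx <- best:(best + L - 1L)
    out[[ci]] <- tibble::tibble(
      cycle_id = cyc$cycle_id,
      start = best, end = best + L,
      start_ms = fs$t_ms[best], end_ms = fs$t_ms[best + L - 1L] + 1000 / rate,
      duration_ms = L * 1000 / rate,
      mean_x = mean(fs$x_smooth[idx]),
      mean_y = mean(fs$y_smooth[idx]),
      mean_speed = min((cs[starts + L] - cs[starts]) / L)
    )
    if (best + L - 1L >= cyc$end) claimed_until <- best + L - 1L
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(cycle_id = integer(0), start = integer(0),
                          end = integer(0), start_ms = numeric(0),
                          end_ms = numeric(0), duration_ms = numeric(0),
                          mean_x = numeric(0), mean_y = numeric(0),
                          mean_speed = numeric(0))
  }
  res
}

#' Point of regard for a calibration target
#'
#' The point of regard (POR) is the per-coordinate median gaze position
#' over every sample of every detected foveation falling inside the
#' target's display interval (after the initial take-up-fixation skip).
#' The median is robust to outlying foveations and biases the estimate
#' toward the slower portion of each window.
#'
#' @param fs filtered-signal tibble.
#' @param foveations foveation tibble from [detect_foveations()].
#' @param target one-row manifest entry (`target_id`, `target_x_deg`,
#'   `target_y_deg`, `start_ms`, `end_ms`).
#' @param skip_initial_ms leading portion of the interval to skip.
#' @return one-row tibble: `target_id`, `x_raw`, `y_raw`, `n_foveations`,
#'   `n_samples`, `target_x_deg`, `target_y_deg`.
#' @export
point_of_regard <- function(fs, foveations, target, skip_initial_ms = 300) {
  t0 <- target$start_ms + skip_initial_ms
  t1 <- target$end_ms
  idx_list <- purrr::pmap(
    list(foveations$start, foveations$end),
    function(s, e) {
      i <- s:(e - 1L)
      i[fs$t_ms[i] >= t0 & fs$t_ms[i] < t1]
    }
  )
  contributing <- vapply(idx_list, length, integer(1)) > 0
  if (!any(contributing)) {
    stop(sprintf("no foveations detected for target %s: cannot compute POR",
                 format(target$target_id)))
  }
  idx <- unlist(idx_list[contributing])
  tibble::tibble(
    target_id = target$target_id,
    x_raw = stats::median(fs$x_smooth[idx]),
    y_raw = stats::median(fs$y_smooth[idx]),
    n_foveations = sum(contributing),
    n_samples = length(idx),
    target_x_deg = target$target_x_deg,
    target_y_deg = target$target_y_deg
  )
}

#' Points of regard for every target in a manifest
#'
#' @param fs filtered-signal tibble.
#' @param foveations foveation tibble.
#' @param manifest manifest tibble (see [read_manifest()]).
#' @param skip_initial_ms leading skip per target; defaults to the
#'   manifest attribute, else 300 ms.
#' @return tibble with one row per target (see [point_of_regard()]).
#' @export
por_table <- function(fs, foveations, manifest, skip_initial_ms = NULL) {
  skip <- skip_initial_ms %||% attr(manifest, "skip_initial_ms") %||% 300
  dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    point_of_regard(fs, foveations, manifest[i, ], skip_initial_ms = skip)
  }))
}
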