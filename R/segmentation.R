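#' Primary nystagmus axis
#'
#' The oscillation axis is taken to be the one with the larger standard
#' deviation of the (smoothed, valid) position signal; infantile nystagmus
#' is primarily horizontal, and ties resolve to horizontal.
#'
#' @param fs filtered-signal tibble (or a raw recording).
#' @return `"horizontal"` or `"vertical"`.
#' @export
primary_axis <- function(fs) {
  px <- if ("x_smooth" %in% names(fs)) fs$x_smooth else fs$x
  py <- if ("y_smooth" %in% names(fs)) fs$y_smooth else fs$y
  sx <- stats::sd(px[fs$valid], na.rm = TRUE)
  sy <- stats::sd(py[fs$valid], na.rm = TRUE)
  if (is.na(sx) || is.na(sy)) stop("an axis has fewer than 2 valid samples")
  if (sy > sx) "vertical" else "horizontal"
}

primary_position <- function(fs) {
  if (identical(fs$axis[1], "vertical")) fs$y_smooth else fs$x_smooth
}

# Dominant oscillation frequency from the autocorrelation of the
# primary-axis position, searched between lo_hz and hi_hz.
dominant_frequency <- function(p, rate, lo_hz = 0.5, hi_hz = 10) {
  ok <- is.finite(p)
  if (sum(ok) < 4) return(NA_real_)
  # bridge gaps linearly so the lag structure survives masked samples
  pf <- stats::approx(seq_along(p)[ok], p[ok], xout = seq_along(p),
                      rule = 2)$y
  pf <- pf - mean(pf)
  max_lag <- min(length(pf) - 1L, ceiling(rate / lo_hz))
  ac <- stats::acf(pf, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]   # ac[k+1] = lag k
  k <- seq_len(max_lag - 1L)[-1]                 # interior lags 2..max-1
  in_range <- k >= floor(rate / hi_hz) & k <= ceiling(rate / lo_hz)
  if (!any(in_range)) return(NA_real_)
  kk <- k[in_range]
  # global autocorrelation maximum in the physiological band: the
  # fundamental period dominates its harmonics
  lag <- kk[which.max(ac[kk + 1L])]
  rate / lag
}

# Local maxima of x with a minimum topographic prominence and minimum
# separation (greedy, highest peak first). NA samples cannot be peaks and
# bound the prominence search.
find_peaks <- function(x, min_prominence, min_distance) {
  n <- length(x)
  xx <- ifelse(is.finite(x), x, -Inf)
  cand <- which(xx > c(-Inf, xx[-n]) & xx >= c(xx[-1], -Inf) &
                  is.finite(x))
  if (length(cand) == 0) return(integer(0))
  m <- length(cand)
  h <- xx[cand]
  # valley[j]: lowest point between candidate peaks j and j+1; edge
  # valleys run to the signal boundaries
  valley_l0 <- min(xx[seq_len(cand[1])])
  valley_r0 <- min(xx[cand[m]:n])
  valley <- if (m > 1) {
    vapply(seq_len(m - 1L), function(j) min(xx[cand[j]:cand[j + 1L]]),
           numeric(1))
  } else numeric(0)
  prom <- vapply(seq_len(m), function(i) {
    base_l <- valley_l0
    j <- i - 1L; run <- Inf
    while (j >= 1L) {
      run <- min(run, valley[j])
      if (h[j] > h[i]) { base_l <- run; break }
      j <- j - 1L
      if (j == 0L) base_l <- min(run, valley_l0)
    }
    base_r <- valley_r0
    j <- i; run <- Inf
    while (j <= m - 1L) {
      run <- min(run, valley[j])
      if (h[j + 1L] > h[i]) { base_r <- run; break }
      j <- j + 1L
      if (j == m) base_r <- min(run, valley_r0)
    }
    # key saddle is the higher of the two side bases (topographic
    # prominence); a gap (-Inf) on one side therefore never inflates it
    h[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(integer(0))
  # enforce separation, keeping the higher peak
  keep <- keep[order(xx[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (all(abs(i - sel) >= min_distance)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Split a nystagmus waveform into cycles
#'
#' Cycle boundaries are successive peaks of the primary-axis smoothed
#' position. The peak finder is scale-free: the minimum peak separation is
#' half the dominant period (estimated from the autocorrelation, searched
#' over 0.5-10 Hz) and the minimum prominence a fraction of the
#' interquartile range of the position signal, so the result is invariant
#' under any affine transform of the raw units with positive gain. For
#' waveforms whose foveations sit at troughs, `peak_polarity = "auto"`
#' picks the polarity whose extrema have the lower local speed.
#'
#' Samples before the first and after the last detected peak belong to no
#' cycle. A cycle is complete when every sample it spans is valid.
#'
#' @param fs filtered-signal tibble from [filter_gaze()].
#' @param config a [pipeline_config()].
#' @return tibble with one row per cycle: `cycle_id`, `start`, `peak`,
#'   `end` (sample indices; the cycle owns samples `[start, end)`, `peak`
#'   is the interior opposite extremum), `complete`.
#' @export
split_cycles <- function(fs, config = pipeline_config()) {
  rate <- sample_rate(fs)
  p <- primary_position(fs)
  p[!fs$valid] <- NA_real_
  f_hat <- dominant_frequency(p, rate)
  empty <- tibble::tibble(cycle_id = integer(0), start = integer(0),
                          peak = integer(0), end = integer(0),
                          complete = logical(0))
  if (!is.finite(f_hat)) return(empty)
  min_dist <- max(2, floor(0.5 * rate / f_hat))
  prom <- config$peak_prominence_frac *
    stats::IQR(p, na.rm = TRUE)
  if (!is.finite(prom) || prom <= 0) return(empty)

  peaks_for <- function(sig) find_peaks(sig, prom, min_dist)
  pol <- config$peak_polarity
  if (pol == "auto") {
    up <- peaks_for(p)
    dn <- peaks_for(-p)
    spd_at <- function(idx) {
      if (length(idx) == 0) return(Inf)
      mean(fs$speed[idx], na.rm = TRUE)
    }
    pol <- if (spd_at(dn) < spd_at(up)) "troughs" else "peaks"
  }
  sig <- if (pol == "troughs") -p else p
  pk <- peaks_for(sig)
  if (length(pk) < 2) return(empty)

  starts <- pk[-length(pk)]
  ends <- pk[-1]
  interior <- mapply(function(s, e) {
    seg <- sig[s:e]
    s - 1L + which.min(ifelse(is.finite(seg), seg, Inf))
  }, starts, ends)
  complete <- mapply(function(s, e) all(fs$valid[s:e]), starts, ends)
  tibble::tibble(cycle_id = seq_along(starts),
                 start = as.integer(starts),
                 peak = as.integer(interior),
                 end = as.integer(ends),
                 complete = as.logical(complete))
}

#' Detect quick phases (saccades) without calibration
#'
#' Uses only relative speed statistics, so detection is invariant under
#' any positive rescaling of the raw units: a sample is a saccade
#' candidate when its speed exceeds the median plus `saccade_k` median
#' absolute deviations of the valid-sample speed. Candidate runs closer
#' than `merge_ms` merge, runs shorter than `min_saccade_ms` are
#' discarded, and each surviving run is extended forward and backward to
#' the nearest local speed minimum to capture the full saccade.
#'
#' Slow phases are all valid samples where no saccade is occurring.
#'
#' @param fs filtered-signal tibble with a `speed` column.
#' @param config a [pipeline_config()].
#' @return `fs` with an added `phase` column in
#'   `c("quick", "slow", "invalid")`.
#' @export
detect_quick_phases <- function(fs, config = pipeline_config()) {
  rate <- sample_rate(fs)
  spd <- fs$speed
  ok <- fs$valid & is.finite(spd)
  # speeds at the rounding-error scale of the position signal are exact
  # zeros for detection purposes (keeps a constant trace saccade-free
  # without breaking scale invariance)
  p <- primary_position(fs)
  floor_spd <- 1e-9 * rate * max(abs(p[ok]), 0, na.rm = TRUE)
  spd <- ifelse(ok & spd < floor_spd, 0, spd)
  med <- stats::median(spd[ok])
  madv <- stats::mad(spd[ok])
  thr <- med + config$saccade_k * madv
  cand <- ok & spd > thr

  if (any(cand)) {
    # merge candidate runs separated by < merge_ms
    runs <- mask_runs(cand)
    if (nrow(runs) > 1) {
      gap_ms <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) * 1000 / rate
      for (i in which(gap_ms < config$merge_ms)) {
        cand[runs$end[i]:runs$start[i + 1L]] <- TRUE
      }
    }
    # drop runs shorter than min_saccade_ms
    runs <- mask_runs(cand)
    dur_ms <- (runs$end - runs$start + 1L) * 1000 / rate
    for (i in which(dur_ms < config$min_saccade_ms)) {
      cand[runs$start[i]:runs$end[i]] <- FALSE
    }
    # extend each run to the nearest local speed minimum
    runs <- mask_runs(cand)
    n <- nrow(fs)
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]
      while (s > 1L && ok[s - 1L] && !cand[s - 1L] &&
               is.finite(spd[s - 1L]) && spd[s - 1L] < spd[s]) {
        s <- s - 1L
      }
      e <- runs$end[i]
      while (e < n && ok[e + 1L] && !cand[e + 1L] &&
               is.finite(spd[e + 1L]) && spd[e + 1L] < spd[e]) {
        e <- e + 1L
      }
      cand[s:e] <- TRUE
    }
  }
  fs$phase <- dplyr::case_when(
    !fs$valid ~ "invalid",
    cand ~ "quick",
    .default = "slow"
  )
  fs
}

#' Keep complete cycles only
#'
#' Foveations are sought in complete cycles only, i.e. cycles that contain
#' no blinks or tracking losses.
#'
#' @param cycles cycle tibble from [split_cycles()].
#' @return the subset of rows with `complete = TRUE`, order preserved.
#' @export
complete_cycles <- function(cycles) {
  dplyr::filter(cycles, .data$complete)
}
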