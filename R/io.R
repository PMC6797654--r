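#' Construct a gaze recording tibble
#'
#' The package represents a recording as a plain tibble with one row per
#' sample: `t_ms` (timestamp, ms), `x`, `y` (position in arbitrary tracker
#' units), and `valid` (logical). Invalid samples keep `NA` positions.
#' Timestamps must be strictly increasing and near-uniform, and the
#' sampling rate must be at least `min_rate_hz` (quick-phase dynamics are
#' not resolvable below roughly 200 Hz).
#'
#' @param t_ms numeric timestamps in milliseconds.
#' @param x,y positions in arbitrary units (`NA` allowed where invalid).
#' @param valid logical validity mask; defaults to non-missing positions.
#' @param min_rate_hz minimum acceptable sampling rate in Hz.
#' @return tibble with columns `t_ms`, `x`, `y`, `valid`.
#' @export
gaze_recording <- function(t_ms, x, y, valid = NULL, min_rate_hz = 200) {
  n <- length(t_ms)
  stopifnot(n >= 2, length(x) == n, length(y) == n)
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  valid <- as.logical(valid) & is.finite(x) & is.finite(y)
  dt <- diff(t_ms)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  dt_med <- stats::median(dt)
  if (any(abs(dt - dt_med) > 0.1 * dt_med)) {
    stop("inter-sample interval is not uniform within 10%")
  }
  rate <- 1000 / dt_med
  if (rate < min_rate_hz) {
    stop(sprintf("sampling rate %.0f Hz is below the %.0f Hz minimum",
                 rate, min_rate_hz))
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  tibble::tibble(t_ms = as.numeric(t_ms), x = as.numeric(x),
                 y = as.numeric(y), valid = valid)
}

#' Sampling rate of a recording
#'
#' @param rec a recording or filtered-signal tibble with a `t_ms` column.
#' @return rate in Hz (1000 / median inter-sample interval).
#' @export
sample_rate <- function(rec) 1000 / stats::median(diff(rec$t_ms))

#' Read a gaze recording
#'
#' Reads a recording from delimited text or from a minimal EyeLink-ASC
#' sample dialect. The CSV dialect requires a header with columns
#' `t_ms,x,y` and an optional `valid` column (missing positions or
#' `valid = 0`/`FALSE` mark a sample invalid). The ASC subset parses only
#' numeric SAMPLE lines (`time x y pupil`) and SBLINK/EBLINK events;
#' everything else is ignored. Tracker-flagged losses (`.` fields, blink
#' events) become `valid = FALSE`.
#'
#' @param path file path.
#' @param format `"csv"` (comma or tab delimited) or `"asc"`.
#' @param min_rate_hz minimum acceptable sampling rate in Hz.
#' @return a recording tibble (see [gaze_recording()]).
#' @export
read_recording <- function(path, format = c("csv", "asc"),
                           min_rate_hz = 200) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    need <- c("t_ms", "x", "y")
    if (!all(need %in% names(df))) {
      stop("CSV must have columns t_ms,x,y (optional valid)")
    }
    valid <- if ("valid" %in% names(df)) {
      as.logical(df$valid) | df$valid == 1
    } else rep(TRUE, nrow(df))
    valid[is.na(valid)] <- FALSE
    gaze_recording(df$t_ms, suppressWarnings(as.numeric(df$x)),
                   suppressWarnings(as.numeric(df$y)),
                   valid = valid, min_rate_hz = min_rate_hz)
  } else {
    read_asc_subset(path, min_rate_hz)
  }
}

read_asc_subset <- function(path, min_rate_hz) {
  lines <- readLines(path, warn = FALSE)
  is_sample <- grepl("^[0-9]+[ \t]", lines)
  smp <- lines[is_sample]
  if (length(smp) < 2) stop("no SAMPLE lines found in ASC file")
  fields <- strsplit(trimws(smp), "[ \t]+")
  t_ms <- vapply(fields, function(f) as.numeric(f[[1]]), numeric(1))
  num <- function(f, i) {
    if (length(f) < i || f[[i]] == ".") NA_real_
    else suppressWarnings(as.numeric(f[[i]]))
  }
  x <- vapply(fields, num, numeric(1), i = 2L)
  y <- vapply(fields, num, numeric(1), i = 3L)
  valid <- is.finite(x) & is.finite(y)
  # EBLINK <eye> <start> <end>: invalidate the spanned samples
  for (ln in lines[grepl("^EBLINK", lines)]) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) >= 4) {
      t0 <- suppressWarnings(as.numeric(f[[3]]))
      t1 <- suppressWarnings(as.numeric(f[[4]]))
      if (is.finite(t0) && is.finite(t1)) valid[t_ms >= t0 & t_ms <= t1] <- FALSE
    }
  }
  gaze_recording(t_ms, x, y, valid = valid, min_rate_hz = min_rate_hz)
}

#' Write a recording as CSV
#'
#' @param rec recording tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  out <- rec[, c("t_ms", "x", "y", "valid")]
  out$valid <- as.integer(out$valid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Data-capture quality check
#'
#' Fraction of valid samples; recordings capturing less than the threshold
#' (default 85%) are flagged. The check is advisory: a warning is raised
#' but processing may continue.
#'
#' @param rec recording tibble.
#' @param capture_threshold minimum acceptable capture fraction.
#' @param warn raise a warning when the check fails.
#' @return one-row tibble with `n_samples`, `n_valid`, `capture`, `pass`.
#' @export
check_capture <- function(rec, capture_threshold = 0.85, warn = TRUE) {
  stopifnot(nrow(rec) > 0)
  capture <- mean(rec$valid)
  pass <- capture >= capture_threshold
  if (!pass && warn) {
    warning(sprintf("poor data capture: %.1f%% valid (threshold %.0f%%)",
                    100 * capture, 100 * capture_threshold))
  }
  tibble::tibble(n_samples = nrow(rec), n_valid = sum(rec$valid),
                 capture = capture, pass = pass)
}

#' Read or write a session manifest
#'
#' A manifest lists the calibration targets: for each, the true screen
#' coordinates in degrees and the interval during which it was displayed.
#' Stored as YAML with top-level keys `skip_initial_ms`, `dwell_ms`, and
#' `targets` (list of `target_x_deg`, `target_y_deg`, `start_ms`,
#' `end_ms`).
#'
#' @param path file path.
#' @return tibble with one row per target plus attributes
#'   `skip_initial_ms` and `dwell_ms`.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  tg <- dplyr::bind_rows(lapply(m$targets, tibble::as_tibble))
  validate_manifest(tg)
  attr(tg, "skip_initial_ms") <- m$skip_initial_ms %||% 300
  attr(tg, "dwell_ms") <- m$dwell_ms %||% 10000
  tg
}

#' @rdname read_manifest
#' @param manifest manifest tibble (columns `target_id`, `target_x_deg`,
#'   `target_y_deg`, `start_ms`, `end_ms`).
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  yaml::write_yaml(list(
    skip_initial_ms = attr(manifest, "skip_initial_ms") %||% 300,
    dwell_ms = attr(manifest, "dwell_ms") %||% 10000,
    targets = lapply(seq_len(nrow(manifest)), function(i) {
      as.list(manifest[i, c("target_id", "target_x_deg", "target_y_deg",
                            "start_ms", "end_ms")])
    })
  ), path)
  invisible(path)
}

validate_manifest <- function(manifest) {
  need <- c("target_x_deg", "target_y_deg", "start_ms", "end_ms")
  stopifnot(all(need %in% names(manifest)))
  if (!"target_id" %in% names(manifest)) {
    manifest$target_id <- seq_len(nrow(manifest))
  }
  o <- order(manifest$start_ms)
  s <- manifest$start_ms[o]; e <- manifest$end_ms[o]
  if (any(s >= e)) stop("manifest: empty or inverted target interval")
  if (nrow(manifest) > 1 && any(s[-1] < e[-length(e)])) {
    stop("manifest: target intervals overlap")
  }
  invisible(manifest)
}

#' Default five-point calibration manifest
#'
#' Targets at the screen centre and +/- 5 deg horizontally, +/- 3 deg
#' vertically, displayed sequentially for `dwell_ms` each.
#'
#' @param dwell_ms display duration per target (ms).
#' @param skip_initial_ms leading interval excluded from analysis (ms).
#' @param start_ms timestamp of the first sample.
#' @return manifest tibble.
#' @export
five_point_manifest <- function(dwell_ms = 10000, skip_initial_ms = 300,
                                start_ms = 0) {
  tx <- c(0, -5, 5, 0, 0)
  ty <- c(0, 0, 0, -3, 3)
  starts <- start_ms + (seq_along(tx) - 1) * dwell_ms
  m <- tibble::tibble(
    target_id = seq_along(tx),
    target_x_deg = tx, target_y_deg = ty,
    start_ms = starts,
    end_ms = starts + dwell_ms
  )
  attr(m, "skip_initial_ms") <- skip_initial_ms
  attr(m, "dwell_ms") <- dwell_ms
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
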