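cal_terms <- function(order) {
  switch(order,
    linear_xtalk = c("(Intercept)", "x_raw", "y_raw"),
    quadratic = c("(Intercept)", "x_raw", "y_raw", "x_raw2", "y_raw2",
                  "x_raw:y_raw"),
    stop("unknown calibration order: ", order)
  )
}

cal_design <- function(x_raw, y_raw, order) {
  X <- cbind(1, x_raw, y_raw)
  if (order == "quadratic") {
    X <- cbind(X, x_raw^2, y_raw^2, x_raw * y_raw)
  }
  colnames(X) <- cal_terms(order)
  X
}

#' Fit the raw-units to degrees calibration
#'
#' Fits, per screen axis, a least-squares polynomial in the two raw gaze
#' coordinates mapping the per-target points of regard to the known
#' target positions in degrees. The default `linear_xtalk` model
#' (`deg = a0 + a1 x_raw + a2 y_raw` per axis) includes the cross-talk
#' term coupling the two raw axes, which absorbs any rotation of the
#' calibration field such as head tilt; it inverts any affine-plus-
#' rotation raw mapping exactly and is solvable from a five-point grid.
#' The `quadratic` model adds `x^2`, `y^2` and `xy` terms and needs at
#' least six non-degenerate targets.
#'
#' Screen coordinates are centred, rightward and upward positive.
#'
#' @param por POR tibble from [por_table()] (columns `x_raw`, `y_raw`,
#'   `target_x_deg`, `target_y_deg`).
#' @param order `"linear_xtalk"` or `"quadratic"`.
#' @return object of class `nyst_calibration`: coefficients per axis,
#'   the fitted target grid, and per-target residuals in degrees.
#' @export
fit_calibration <- function(por, order = c("linear_xtalk", "quadratic")) {
  order <- match.arg(order)
  k <- length(cal_terms(order))
  if (nrow(por) < k) {
    stop(sprintf("%s calibration needs at least %d targets, got %d",
                 order, k, nrow(por)))
  }
  X <- cal_design(por$x_raw, por$y_raw, order)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("rank-deficient calibration design: identical points of regard ",
         "or collinear targets")
  }
  coef_x <- qr.coef(qr_x, por$target_x_deg)
  coef_y <- qr.coef(qr_x, por$target_y_deg)
  pred_x <- drop(X %*% coef_x)
  pred_y <- drop(X %*% coef_y)
  residuals <- tibble::tibble(
    target_id = por$target_id %||% seq_len(nrow(por)),
    target_x_deg = por$target_x_deg,
    target_y_deg = por$target_y_deg,
    pred_x_deg = pred_x,
    pred_y_deg = pred_y,
    resid_x_deg = abs(pred_x - por$target_x_deg),
    resid_y_deg = abs(pred_y - por$target_y_deg),
    resid_deg = sqrt((pred_x - por$target_x_deg)^2 +
                       (pred_y - por$target_y_deg)^2)
  )
  structure(list(
    order = order,
    coef = list(x = stats::setNames(as.numeric(coef_x), cal_terms(order)),
                y = stats::setNames(as.numeric(coef_y), cal_terms(order))),
    targets = por[, intersect(c("target_id", "target_x_deg", "target_y_deg",
                                "x_raw", "y_raw"), names(por))],
    residuals = residuals,
    fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "nyst_calibration")
}

#' Apply a calibration to raw gaze data
#'
#' Each axis is transformed separately using its stored coefficients;
#' timestamps and the validity mask pass through unchanged.
#'
#' @param model a fitted `nyst_calibration`.
#' @param rec recording or filtered-signal tibble; smoothed positions are
#'   used when present, raw otherwise.
#' @return tibble `t_ms`, `x_deg`, `y_deg`, `valid` (plus `speed_deg_s`
#'   when the input carries a primary-axis velocity).
#' @export
apply_calibration <- function(model, rec) {
  stopifnot(inherits(model, "nyst_calibration"))
  xr <- if ("x_smooth" %in% names(rec)) rec$x_smooth else rec$x
  yr <- if ("y_smooth" %in% names(rec)) rec$y_smooth else rec$y
  X <- cal_design(xr, yr, model$order)
  out <- tibble::tibble(
    t_ms = rec$t_ms,
    x_deg = drop(X %*% model$coef$x),
    y_deg = drop(X %*% model$coef$y),
    valid = rec$valid
  )
  if (all(c("vel_x", "vel_y", "axis") %in% names(rec))) {
    # linear part of the map converts raw velocity to deg/s exactly for
    # linear_xtalk; for quadratic it is the local gain at small signals
    out$vel_x_deg_s <- model$coef$x[["x_raw"]] * rec$vel_x +
      model$coef$x[["y_raw"]] * rec$vel_y
    out$vel_y_deg_s <- model$coef$y[["x_raw"]] * rec$vel_x +
      model$coef$y[["y_raw"]] * rec$vel_y
    out$speed_deg_s <- abs(
      if (identical(rec$axis[1], "vertical")) out$vel_y_deg_s else out$vel_x_deg_s
    )
    out$axis <- rec$axis
  }
  if ("phase" %in% names(rec)) out$phase <- rec$phase
  out
}

#' Drift-correct a calibration from a single fixation target
#'
#' Head movements during a long session shift the mapping by a roughly
#' constant offset. Given a short recording of fixation on one known
#' target, the foveation pipeline locates the point of regard, and a
#' per-axis additive constant is composed with the model so that this POR
#' maps exactly onto the target; all other coefficients are unchanged.
#'
#' @param model a fitted `nyst_calibration`.
#' @param rec drift-check recording (raw units, same frame as the fit).
#' @param target_deg numeric length-2: the fixation target `(x, y)` in
#'   degrees.
#' @param config a [pipeline_config()].
#' @param skip_initial_ms leading interval excluded from the POR.
#' @return the corrected `nyst_calibration`.
#' @export
drift_correct <- function(model, rec, target_deg,
                          config = pipeline_config(),
                          skip_initial_ms = NULL) {
  stopifnot(inherits(model, "nyst_calibration"), length(target_deg) == 2)
  seg <- segment_waveform(rec, config)
  if (nrow(seg$foveations) == 0) {
    stop("no foveations detected in drift recording")
  }
  skip <- skip_initial_ms %||% config$skip_initial_ms
  target <- tibble::tibble(target_id = "drift",
                           target_x_deg = target_deg[1],
                           target_y_deg = target_deg[2],
                           start_ms = rec$t_ms[1],
                           end_ms = rec$t_ms[nrow(rec)] + 1)
  por <- point_of_regard(seg$fs, seg$foveations, target,
                         skip_initial_ms = skip)
  X <- cal_design(por$x_raw, por$y_raw, model$order)
  off_x <- target_deg[1] - drop(X %*% model$coef$x)
  off_y <- target_deg[2] - drop(X %*% model$coef$y)
  model$coef$x[["(Intercept)"]] <- model$coef$x[["(Intercept)"]] + off_x
  model$coef$y[["(Intercept)"]] <- model$coef$y[["(Intercept)"]] + off_y
  model$drift_offset_deg <- c(x = off_x, y = off_y)
  model
}

#' Save a calibration to a JSON file
#'
#' The round trip through [read_calibration()] is lossless to full
#' stored precision; zero coefficients (for example a cross-talk term of
#' zero) are written explicitly, never dropped.
#'
#' @param model a fitted `nyst_calibration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "nyst_calibration"))
  obj <- list(
    version = 1L,
    fitted_at = model$fitted_at,
    order = model$order,
    axes = list(x = list(coeffs = as.list(model$coef$x)),
                y = list(coeffs = as.list(model$coef$y))),
    targets_deg = model$targets,
    residuals_deg = model$residuals
  )
  # 17 significant digits uniquely identify a double: lossless round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported or missing calibration file version")
  }
  order <- obj$order %||% stop("calibration file missing model order")
  terms <- cal_terms(order)
  get_axis <- function(ax) {
    cc <- obj$axes[[ax]]$coeffs
    if (is.null(cc) || !all(terms %in% names(cc))) {
      stop("calibration file missing coefficient block for axis ", ax)
    }
    stats::setNames(vapply(cc[terms], as.numeric, numeric(1)), terms)
  }
  structure(list(
    order = order,
    coef = list(x = get_axis("x"), y = get_axis("y")),
    targets = tibble::as_tibble(obj$targets_deg),
    residuals = tibble::as_tibble(obj$residuals_deg),
    fitted_at = obj$fitted_at
  ), class = "nyst_calibration")
}

#' @export
print.nyst_calibration <- function(x, ...) {
  cat("<nyst_calibration>", x$order, "model,",
      nrow(x$targets), "targets\n")
  cat("  x:", paste(sprintf("%s=%.6g", names(x$coef$x), x$coef$x),
                    collapse = ", "), "\n")
  cat("  y:", paste(sprintf("%s=%.6g", names(x$coef$y), x$coef$y),
                    collapse = ", "), "\n")
  cat(sprintf("  max residual %.4g deg\n", max(x$residuals$resid_deg)))
  invisible(x)
}

#' Tidy a calibration model
#'
#' @param x a `nyst_calibration`.
#' @param ... unused.
#' @return tibble with one row per axis/term: `axis`, `term`, `estimate`.
#' @method tidy nyst_calibration
#' @export
tidy.nyst_calibration <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(axis = "x", term = names(x$coef$x),
                   estimate = unname(x$coef$x)),
    tibble::tibble(axis = "y", term = names(x$coef$y),
                   estimate = unname(x$coef$y))
  )
}

#' Glance at a calibration model
#'
#' @param x a `nyst_calibration`.
#' @param ... unused.
#' @return one-row tibble: `order`, `n_targets`, `rms_resid_deg`,
#'   `max_resid_deg`.
#' @method glance nyst_calibration
#' @export
glance.nyst_calibration <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    n_targets = nrow(x$residuals),
    rms_resid_deg = sqrt(mean(x$residuals$resid_deg^2)),
    max_resid_deg = max(x$residuals$resid_deg)
  )
}

#' Plot calibration residuals
#'
#' Shows the fitted target grid with arrows from each predicted point of
#' regard (in degrees) to its true target position.
#'
#' @param object a `nyst_calibration`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nyst_calibration
#' @export
autoplot.nyst_calibration <- function(object, ...) {
  r <- object$residuals
  ggplot2::ggplot(r, ggplot2::aes(x = .data$target_x_deg,
                                  y = .data$target_y_deg)) +
    ggplot2::geom_point(shape = 3, size = 3) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$pred_x_deg, y = .data$pred_y_deg,
                   xend = .data$target_x_deg, yend = .data$target_y_deg),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$pred_x_deg,
                                     y = .data$pred_y_deg),
                        colour = "firebrick", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "horizontal (deg)", y = "vertical (deg)",
                  title = "Calibration residuals",
                  subtitle = sprintf("max residual %.3g deg",
                                     max(r$resid_deg))) +
    ggplot2::theme_minimal()
}
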