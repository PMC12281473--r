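#' Percent-enhancement (TOLD) curve from a T1-weighted time series
#'
#' Reduces the series to the TOLD signal
#' `dM% = 100 * (M - Mbase) / Mbase`, where `Mbase` is the mean
#' intensity over the baseline frames (the pre-challenge air period).
#' In ROI mode the ROI-mean intensity is formed per frame first and the
#' enhancement computed from it (not the mean of per-pixel
#' enhancements), matching how ROI time courses with per-frame error
#' bars are constructed from intensities. The curve's mean over the
#' baseline window is zero by construction, and the curve is invariant
#' under global intensity scaling of the series.
#'
#' @param series a `told_series`.
#' @param roi logical mask selecting an ROI, or a region name from the
#'   series' label image; mutually exclusive with `pixel`.
#' @param pixel integer `c(y, x)` for a single-pixel curve.
#' @param baseline_frames frame indices of the baseline window; defaults
#'   to the series' own (all frames of the initial air period).
#' @return An object of class `dm_curve`: list with `time_min`, `dm`
#'   (percent), `sd` (per-frame ROI sd of pixel enhancements, ROI mode
#'   only), `source`, `schedule`, `baseline_frames`.
#' @export
compute_dm_percent <- function(series, roi = NULL, pixel = NULL,
                               baseline_frames = series$baseline_frames) {
  stopifnot(inherits(series, "told_series"))
  if (length(baseline_frames) == 0 ||
      any(baseline_frames < 1 | baseline_frames > length(series$time_min)))
    stop("invalid baseline window")
  if (is.null(roi) == is.null(pixel))
    stop("supply exactly one of `roi` or `pixel`")
  n <- length(series$time_min)
  if (!is.null(pixel)) {
    m <- series$data[pixel[1], pixel[2], ]
    src <- sprintf("pixel (%d, %d)", pixel[1], pixel[2])
    sdv <- NULL
  } else {
    if (is.character(roi)) {
      i <- match(roi, series$roi_names)
      if (is.na(i)) stop(sprintf("unknown ROI '%s'", roi))
      src <- roi
      roi <- series$labels == i
    } else src <- "roi"
    roi <- as.array(roi)
    if (!identical(dim(roi), dim(series$data)[1:2]))
      stop("ROI mask shape does not match the image plane")
    if (!any(roi)) stop("empty ROI mask")
    m <- vapply(seq_len(n), function(k) mean(series$data[, , k][roi]), 0)
    # per-frame spread of pixel enhancements, for error bars
    px <- lapply(seq_len(n), function(k) series$data[, , k][roi])
    base_px <- rowMeans(do.call(cbind, px[baseline_frames]))
    sdv <- vapply(seq_len(n), function(k)
      stats::sd(100 * (px[[k]] - base_px) / base_px), 0)
  }
  m_base <- mean(m[baseline_frames])
  if (!is.finite(m_base) || m_base <= 0)
    stop("baseline mean intensity is not positive")
  structure(list(time_min = series$time_min,
                 dm = 100 * (m - m_base) / m_base,
                 sd = sdv, source = src,
                 schedule = series$schedule,
                 baseline_frames = baseline_frames),
            class = "dm_curve")
}

#' Construct an enhancement curve from explicit values
#'
#' Builds a `dm_curve` directly from times and percent-enhancement
#' values, e.g. for curves digitised from plots or produced outside the
#' package.
#'
#' @param time_min frame times in minutes, strictly increasing.
#' @param dm percent-enhancement values, same length.
#' @param source label for the curve origin.
#' @param schedule optional `gas_schedule`.
#' @param baseline_frames indices of the baseline window.
#' @return A `dm_curve`.
#' @export
dm_curve <- function(time_min, dm, source = "user", schedule = NULL,
                     baseline_frames = integer()) {
  stopifnot(length(time_min) == length(dm), !is.unsorted(time_min))
  structure(list(time_min = as.numeric(time_min), dm = as.numeric(dm),
                 sd = NULL, source = source, schedule = schedule,
                 baseline_frames = baseline_frames),
            class = "dm_curve")
}

#' @export
print.dm_curve <- function(x, ...) {
  cat(sprintf("<dm_curve> %s: %d frames over %.3g min, dM%% range %.3g .. %.3g\n",
              x$source, length(x$dm), max(x$time_min),
              min(x$dm), max(x$dm)))
  invisible(x)
}

#' @export
plot.dm_curve <- function(x, ...) {
  graphics::plot(x$time_min, x$dm, xlab = "time (min)",
                 ylab = expression(Delta * "M%"),
                 main = sprintf("TOLD signal, %s", x$source), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(x$schedule))
    graphics::abline(v = x$schedule$start_min[-1], lty = 2, col = "grey")
  invisible(x)
}

#' @export
as.data.frame.dm_curve <- function(x, ...) {
  d <- data.frame(time_min = x$time_min, dm_percent = x$dm)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}

#' Fit the exponential wash-in model to the rising TOLD phase
#'
#' Nonlinear least-squares fit of
#' `S(t) = S_max * (1 - exp(-(t - onset) / T_ox))` to the curve between
#' the challenge onset and the window end. `T_ox` is the time for the
#' signal to reach 63.2% of the plateau `S_max`; its reciprocal
#' `k_ox = 1/T_ox` is the oxygenation rate. Initialisation takes
#' `S_max` from the window maximum and `T_ox` from the first crossing of
#' 63.2% of it; the solver is bounded (`S_max` in (-100, 1000)%, `T_ox`
#' in (0.01, 100) min). Negative-going challenges are handled by
#' initialising from the window minimum when the response is negative.
#'
#' @param curve a `dm_curve`.
#' @param onset challenge onset time (min); default: start of the first
#'   interval whose gas differs from the first interval's.
#' @param window_end end of the fit window (min); default: end of that
#'   challenge interval (the full challenge period).
#' @return An object of class `kinetic_fit` with `coefficients`
#'   (`s_max`, `t_ox`, `k_ox = 1/t_ox`), `converged`, `rss`, the fit
#'   window, and the windowed data. `k_ox * t_ox` is exactly 1.
#' @export
fit_oxygenation <- function(curve, onset = NULL, window_end = NULL) {
  stopifnot(inherits(curve, "dm_curve"))
  if (is.null(onset) || is.null(window_end)) {
    sch <- curve$schedule
    if (is.null(sch)) stop("no schedule attached; supply `onset` and `window_end`")
    ch <- which(abs(sch$o2_fraction - sch$o2_fraction[1]) > 1e-12)[1]
    if (is.na(ch)) stop("schedule contains no gas challenge")
    if (is.null(onset)) onset <- sch$start_min[ch]
    if (is.null(window_end)) window_end <- sch$end_min[ch]
  }
  sel <- curve$time_min >= onset - 1e-9 & curve$time_min <= window_end + 1e-9
  t <- curve$time_min[sel] - onset
  y <- curve$dm[sel]
  if (length(t) < 4)
    stop(sprintf("need at least 4 frames in the fit window, got %d", length(t)))

  negative <- abs(min(y)) > abs(max(y))
  s0 <- if (negative) min(y) else max(y)
  degenerate <- !is.finite(s0) || abs(s0) < 1e-12 || stats::sd(y) == 0
  t0 <- if (!degenerate) {
    cross <- which(if (negative) y <= 0.632 * s0 else y >= 0.632 * s0)[1]
    if (is.na(cross) || t[cross] <= 0) max(t[2], 0.05) else t[cross]
  } else 1
  fit <- NULL
  if (!degenerate)
    fit <- tryCatch(
      stats::nls(y ~ smax * (1 - exp(-t / tox)),
                 start = list(smax = s0, tox = t0),
                 lower = c(smax = -100, tox = 0.01),
                 upper = c(smax = 1000, tox = 100),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(s_max = if (degenerate) mean(y) else NA_real_,
            t_ox = NA_real_, k_ox = NA_real_)
    return(structure(list(coefficients = cf, converged = FALSE,
                          rss = NA_real_, window = c(onset, window_end),
                          time_min = t + onset, dm = y,
                          fitted = rep(NA_real_, length(y)),
                          type = "oxygenation"),
                     class = "kinetic_fit"))
  }
  est <- stats::coef(fit)
  cf <- c(s_max = unname(est["smax"]), t_ox = unname(est["tox"]),
          k_ox = 1 / unname(est["tox"]))
  structure(list(coefficients = cf, converged = TRUE,
                 rss = sum(stats::residuals(fit)^2),
                 window = c(onset, window_end),
                 time_min = t + onset, dm = y,
                 fitted = stats::fitted(fit),
                 type = "oxygenation"),
            class = "kinetic_fit")
}

#' Estimate the O2 consumption rate from the decaying TOLD phase
#'
#' The post-challenge decay is summarised by the slope of the
#' semi-logarithmic plot: a least-squares line is fitted to
#' `ln(dM%)` versus time over the first `n_points` frames strictly
#' after the gas-off time that have positive enhancement, and the
#' consumption rate is `k_oc = -slope`. Non-positive values inside the
#' window cannot be log-transformed; they are excluded and the exclusion
#' reported via a message.
#'
#' @param curve a `dm_curve`.
#' @param offset gas-off time (min); default: end of the first challenge
#'   interval in the attached schedule.
#' @param n_points number of decay points to use (default 5).
#' @return A `kinetic_fit` with `coefficients` (`k_oc`, plus the
#'   semi-log `intercept`), the points used, and `n_excluded`.
#' @export
fit_consumption <- function(curve, offset = NULL, n_points = 5) {
  stopifnot(inherits(curve, "dm_curve"))
  if (is.null(offset)) {
    sch <- curve$schedule
    if (is.null(sch)) stop("no schedule attached; supply `offset`")
    ch <- which(abs(sch$o2_fraction - sch$o2_fraction[1]) > 1e-12)[1]
    if (is.na(ch)) stop("schedule contains no gas challenge")
    offset <- sch$end_min[ch]
  }
  after <- which(curve$time_min > offset + 1e-9)
  pos <- after[curve$dm[after] > 0]
  n_excluded <- sum(curve$dm[after[seq_len(min(length(after),
                                               n_points))]] <= 0)
  if (length(pos) < 2)
    stop("need at least 2 positive dM% values after the gas-off time")
  use <- pos[seq_len(min(n_points, length(pos)))]
  if (n_excluded > 0)
    message(sprintf("fit_consumption: %d non-positive point(s) excluded from the semi-log window",
                    n_excluded))
  t <- curve$time_min[use]; ly <- log(curve$dm[use])
  lmfit <- stats::lm(ly ~ t)
  cf <- stats::coef(lmfit)
  structure(list(coefficients = c(k_oc = -unname(cf[2]),
                                  intercept = unname(cf[1])),
                 converged = TRUE,
                 rss = sum(stats::residuals(lmfit)^2),
                 window = range(t), time_min = t,
                 dm = curve$dm[use], fitted = exp(stats::fitted(lmfit)),
                 n_excluded = n_excluded, type = "consumption"),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$type == "oxygenation") {
    if (!x$converged)
      cat("<kinetic_fit> oxygenation fit did not converge\n")
    else
      cat(sprintf("<kinetic_fit> S_max = %.4g%%, T_ox = %.4g min, k_ox = %.4g /min (rss %.3g)\n",
                  x$coefficients["s_max"], x$coefficients["t_ox"],
                  x$coefficients["k_ox"], x$rss))
  } else {
    cat(sprintf("<kinetic_fit> k_oc = %.4g /min from %d semi-log points (rss %.3g)\n",
                x$coefficients["k_oc"], length(x$time_min), x$rss))
  }
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
residuals.kinetic_fit <- function(object, ...) object$dm - object$fitted

#' @export
predict.kinetic_fit <- function(object, time_min = object$time_min, ...) {
  cf <- object$coefficients
  if (object$type == "oxygenation") {
    unname(cf["s_max"] *
             (1 - exp(-(time_min - object$window[1]) / cf["t_ox"])))
  } else {
    unname(exp(cf["intercept"] - cf["k_oc"] * time_min))
  }
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  logy <- x$type == "consumption"
  graphics::plot(x$time_min, x$dm, log = if (logy) "y" else "",
                 xlab = "time (min)", ylab = expression(Delta * "M%"),
                 main = sprintf("%s fit", x$type), ...)
  tt <- seq(min(x$time_min), max(x$time_min), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Per-pixel TOLD enhancement map
#'
#' Computes, per pixel, the percent enhancement of the challenge-window
#' mean intensity relative to the baseline-window mean, giving a signed
#' map of positive and negative TOLD responses.
#'
#' @param series a `told_series`.
#' @param window_base,window_challenge frame-index windows; defaults:
#'   the series' baseline frames, and the last 5 frames.
#' @return A `scalar_map` in percent; pixels with non-positive baseline
#'   are invalid.
#' @export
map_told <- function(series, window_base = series$baseline_frames,
                     window_challenge = NULL) {
  stopifnot(inherits(series, "told_series"))
  n <- length(series$time_min)
  if (is.null(window_challenge))
    window_challenge <- seq(max(1, n - 4), n)
  for (w in list(window_base, window_challenge))
    if (length(w) == 0 || any(w < 1 | w > n)) stop("invalid frame window")
  base <- apply(series$data[, , window_base, drop = FALSE], c(1, 2), mean)
  chal <- apply(series$data[, , window_challenge, drop = FALSE],
                c(1, 2), mean)
  ok <- is.finite(base) & base > 0
  scalar_map(100 * (chal - base) / base, unit = "%", valid = ok)
}

#' Fit TOLD kinetics for every ROI of a series
#'
#' Convenience wrapper: for each labelled ROI, computes the enhancement
#' curve and runs the wash-in fit and (when a return-to-baseline phase
#' exists) the semi-log consumption fit.
#'
#' @param series a `told_series`.
#' @param n_points decay points for [fit_consumption()].
#' @return A data.frame with one row per ROI: `roi`, `s_max`, `t_ox`,
#'   `k_ox`, `k_oc`, `converged`.
#' @export
fit_told_rois <- function(series, n_points = 5) {
  sch <- series$schedule
  ch <- which(abs(sch$o2_fraction - sch$o2_fraction[1]) > 1e-12)[1]
  has_decay <- !is.na(ch) && ch < nrow(sch)
  rows <- lapply(series$roi_names, function(nm) {
    cv <- compute_dm_percent(series, roi = nm)
    ox <- fit_oxygenation(cv)
    koc <- if (has_decay)
      tryCatch(coef(fit_consumption(cv, n_points = n_points))[["k_oc"]],
               error = function(e) NA_real_) else NA_real_
    data.frame(roi = nm,
               s_max = unname(coef(ox)["s_max"]),
               t_ox = unname(coef(ox)["t_ox"]),
               k_ox = unname(coef(ox)["k_ox"]),
               k_oc = koc, converged = ox$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
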