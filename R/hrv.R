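# Core metric: the HRV amplitude -- the difference between moving-median
# envelopes of local maxima and local minima of the RR-interval series --
# plus sliding-window RMSSD / HR and segment-window averaging.

#' Local extrema of an RR-interval series
#'
#' An interior point `i` is a local maximum when `rr[i] > rr[i-1]` and
#' `rr[i] >= rr[i+1]` (mirrored for minima), so a plateau bounded by strictly
#' smaller (larger) neighbors contributes exactly its first point. Endpoints
#' are never extrema. Indices are 1-based.
#'
#' @param rr An [rr_series()] or numeric vector with >= 3 values.
#' @return A list with integer vectors `max_idx` and `min_idx`.
#' @export
local_extrema <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < 3) stop("need at least 3 points to define local extrema")
  i <- 2:(n - 1)
  max_idx <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  min_idx <- i[x[i] < x[i - 1] & x[i] <= x[i + 1]]
  list(max_idx = as.integer(max_idx), min_idx = as.integer(min_idx))
}

# centered moving median with symmetric shrink at the boundaries
moving_median <- function(v, window) {
  m <- length(v)
  half <- (window - 1) %/% 2
  vapply(seq_len(m), function(j) {
    k <- min(half, j - 1, m - j)
    stats::median(v[(j - k):(j + k)])
  }, 0)
}

#' Moving-median envelope and HRV amplitude of an RR series
#'
#' The upper envelope is the centered moving median over `window` consecutive
#' local-maxima values, anchored at each maximum's time and linearly
#' interpolated to every beat time (constant extrapolation beyond the first
#' and last extremum); the lower envelope is the analog over local minima.
#' The HRV amplitude is their difference, floored at zero. The median makes
#' the envelope robust to isolated outliers while preserving local trends;
#' it is used here in preference to a Hilbert-transform envelope, which
#' behaves poorly on highly entropic RR series.
#'
#' @param rr An [rr_series()].
#' @param window Number of consecutive extrema entering each median. Default
#'   5. At the boundaries (and whenever fewer than `window` extrema exist)
#'   the window shrinks symmetrically and the result is flagged low
#'   confidence.
#' @return An object of class `hrv_amplitude_series`: list with `times`,
#'   `upper`, `lower`, `amplitude` (all per beat, ms) and `low_confidence`.
#' @export
envelope <- function(rr, window = 5) {
  stopifnot(inherits(rr, "rr_series"), window >= 1)
  x <- rr$intervals
  tt <- rr$times
  ext <- if (length(x) >= 3) local_extrema(x)
         else list(max_idx = integer(0), min_idx = integer(0))

  env_one <- function(idx) {
    if (!length(idx)) return(NULL)
    med <- moving_median(x[idx], window)
    if (length(idx) == 1) rep(med, length(tt))
    else stats::approx(tt[idx], med, xout = tt, rule = 2)$y
  }
  upper <- env_one(ext$max_idx)
  lower <- env_one(ext$min_idx)
  if (is.null(upper) || is.null(lower)) {
    # constant or monotone series: no oscillation, amplitude identically 0
    upper <- lower <- x
  }
  amp <- pmax(upper - lower, 0)
  structure(list(times = tt, upper = upper, lower = lower, amplitude = amp,
                 low_confidence = length(ext$max_idx) < window ||
                   length(ext$min_idx) < window),
            class = "hrv_amplitude_series")
}

#' @export
print.hrv_amplitude_series <- function(x, ...) {
  cat(sprintf(
    "<hrv_amplitude_series> %d beats, mean amplitude %.1f ms%s\n",
    length(x$times), mean(x$amplitude),
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' @export
as.data.frame.hrv_amplitude_series <- function(x, ...) {
  data.frame(time_s = x$times, upper = x$upper, lower = x$lower,
             amplitude = x$amplitude)
}

#' HRV amplitude resampled onto a uniform grid
#'
#' Computes the beat-time envelope amplitude and linearly interpolates it to
#' a uniform grid, for segment-window averaging and group-mean time courses.
#'
#' @param rr An [rr_series()].
#' @param window Envelope median window (extrema count), default 5.
#' @param resample_step Grid step, seconds. Default 1.
#' @return A [sliding_metric_series()] with metric `"hrv_amplitude"` (ms).
#' @export
hrv_amplitude_timeseries <- function(rr, window = 5, resample_step = 1) {
  env <- envelope(rr, window)
  t0 <- min(env$times); t1 <- max(env$times)
  grid <- seq(ceiling(t0 / resample_step) * resample_step, t1,
              by = resample_step)
  vals <- stats::approx(env$times, env$amplitude, xout = grid, rule = 2)$y
  sliding_metric_series(grid, vals, valid = rep(TRUE, length(grid)),
                        metric = "hrv_amplitude", step = resample_step)
}

# shared sliding-window machinery over interval times
slide_windows <- function(rr, window, step, fun, min_n, min_span = 0,
                          metric = "metric", align = c("center", "causal")) {
  align <- match.arg(align)
  tt <- rr$times
  t0 <- tt[1] - rr$intervals[1] / 1000
  t1 <- tt[length(tt)]
  grid <- seq(ceiling(t0 / step) * step, t1, by = step)
  lo <- if (align == "center") grid - window / 2 else grid - window
  hi <- if (align == "center") grid + window / 2 else grid
  i0 <- findInterval(lo, tt) + 1L        # first interval with time > lo
  i1 <- findInterval(hi, tt)             # last interval with time <= hi
  vals <- rep(NA_real_, length(grid))
  nb <- integer(length(grid))
  ok <- logical(length(grid))
  for (g in seq_along(grid)) {
    if (i1[g] < i0[g]) next
    idx <- i0[g]:i1[g]
    nb[g] <- length(idx)
    span <- tt[i1[g]] - tt[i0[g]]
    if (nb[g] >= min_n && span >= min_span) {
      vals[g] <- fun(rr$intervals[idx])
      ok[g] <- TRUE
    }
  }
  sliding_metric_series(grid, vals, nb, ok, metric = metric, step = step)
}

#' Sliding-window RMSSD
#'
#' Root mean square of successive differences of the intervals whose times
#' fall in each (by default centered) window -- a short-segment index of
#' vagal cardiac control, computable from segments as short as 10 s.
#'
#' @param rr An [rr_series()].
#' @param window Window length, seconds. Default 30.
#' @param step Grid step, seconds. Default 1.
#' @param min_len Minimum data span inside a window for a valid value,
#'   seconds. Default 10.
#' @param align `"center"` (default) or `"causal"` (trailing window).
#' @return A [sliding_metric_series()] with metric `"rmssd"` (ms); points
#'   with fewer than 3 intervals or spanning under `min_len` are invalid.
#' @export
sliding_rmssd <- function(rr, window = 30, step = 1, min_len = 10,
                          align = "center") {
  stopifnot(inherits(rr, "rr_series"), window >= min_len)
  slide_windows(rr, window, step,
                function(x) sqrt(mean(diff(x)^2)),
                min_n = 3L, min_span = min_len, metric = "rmssd",
                align = align)
}

#' Sliding-window heart rate
#'
#' HR in bpm = 60000 / mean RR interval (ms) over each window.
#'
#' @inheritParams sliding_rmssd
#' @return A [sliding_metric_series()] with metric `"hr"` (bpm); empty
#'   windows are invalid.
#' @export
sliding_hr <- function(rr, window = 30, step = 1, align = "center") {
  stopifnot(inherits(rr, "rr_series"))
  slide_windows(rr, window, step,
                function(x) 60000 / mean(x),
                min_n = 1L, metric = "hr", align = align)
}

#' Average a metric time series over labeled segment windows
#'
#' Means of valid grid points falling in each `[start, end)` window, plus
#' optional label aggregates (e.g. the mean of two chapters), computed as the
#' unweighted mean of the member-window means.
#'
#' @param series A [sliding_metric_series()].
#' @param windows A [segment_windows()] data frame.
#' @param aggregates Named list mapping an aggregate label to the member
#'   window labels, e.g. `list("ch4+ch7" = c("ch4", "ch7"))`.
#' @return A data frame `label, metric, mean, n_points`; a window with zero
#'   valid points yields `NA` with a message.
#' @export
window_average <- function(series, windows, aggregates = list()) {
  stopifnot(inherits(series, "sliding_metric_series"))
  tr <- range(series$times)
  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(k) {
    s <- windows$start[k]; e <- windows$end[k]
    if (s < tr[1] || e > tr[2] + series$step)
      warning(sprintf("window '%s' [%g, %g) clipped to series span [%g, %g]",
                      windows$label[k], s, e, tr[1], tr[2]))
    sel <- series$times >= s & series$times < e & series$valid
    n <- sum(sel)
    if (!n) message(sprintf("window '%s' has no valid points", windows$label[k]))
    data.frame(label = windows$label[k], metric = series$metric,
               mean = if (n) mean(series$values[sel]) else NA_real_,
               n_points = n, stringsAsFactors = FALSE)
  }))
  for (lab in names(aggregates)) {
    member <- out$mean[match(aggregates[[lab]], out$label)]
    out <- rbind(out, data.frame(
      label = lab, metric = series$metric,
      mean = mean(member), n_points = sum(out$n_points[
        match(aggregates[[lab]], out$label)]),
      stringsAsFactors = FALSE))
  }
  out
}
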