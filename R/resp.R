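# Respiration chain: Butterworth band-pass -> breath detection ->
# per-breath rate / amplitude series.

#' Zero-phase Butterworth band-pass for respiration
#'
#' Second-order 0.05-3 Hz band-pass applied forward and backward
#' (zero-phase), removing baseline drift and high-frequency noise while
#' passing every physiologic breathing rate (3-180 breaths/min).
#'
#' @param rec A [resp_recording()] sampled above 6 Hz.
#' @param low,high Band edges, Hz.
#' @param order Filter order per pass. Default 2.
#' @return A filtered [resp_recording()].
#' @export
preprocess_resp <- function(rec, low = 0.05, high = 3, order = 2) {
  stopifnot(inherits(rec, "resp_recording"))
  if (rec$sampling_rate <= 6)
    stop("respiration sampling rate must exceed 6 Hz")
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  bw <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # remove the mean first: the 0.05 Hz high-pass edge decays slowly, and a
  # large DC offset would otherwise bleed into the first breaths
  y <- signal::filtfilt(bw, rec$samples - mean(rec$samples))
  resp_recording(y, rec$sampling_rate, rec$t0)
}

#' Construct a breath series
#'
#' @param peak_times End-inspiration times, seconds.
#' @param trough_times End-expiration times, seconds (each preceding its peak).
#' @param amplitude Per-breath amplitude: peak minus preceding trough,
#'   signal units.
#' @param rate Per-breath instantaneous rate, breaths/min (NA for the first
#'   breath).
#' @return An object of class `breath_series`.
#' @export
breath_series <- function(peak_times, trough_times, amplitude, rate) {
  stopifnot(length(peak_times) == length(trough_times),
            length(peak_times) == length(amplitude))
  if (any(amplitude < 0)) stop("breath amplitudes must be >= 0")
  structure(list(peak_times = peak_times, trough_times = trough_times,
                 amplitude = amplitude, rate = rate),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths, median rate %.1f /min\n",
              length(x$peak_times),
              stats::median(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' Detect breaths in a filtered respiration signal
#'
#' Zero-crossing-bracketed extremum search: each positive half-wave between
#' an up- and a down-crossing yields a candidate peak (end-inspiration), each
#' negative half-wave a trough (end-expiration). Breaths shorter than
#' `min_duration` or smaller than an adaptive amplitude floor (a fraction of
#' the median candidate amplitude) are rejected.
#'
#' @param rec A [resp_recording()], already band-passed (see
#'   [preprocess_resp()]).
#' @param min_duration Minimum breath-to-breath interval, seconds (default
#'   1.5, i.e. at most 40 breaths/min).
#' @param amp_floor_frac Amplitude floor as a fraction of the median
#'   candidate breath amplitude.
#' @return A [breath_series()]; empty (with a warning) when no breaths are
#'   found.
#' @export
detect_breaths <- function(rec, min_duration = 1.5, amp_floor_frac = 0.3) {
  stopifnot(inherits(rec, "resp_recording"))
  x <- rec$samples - stats::median(rec$samples)
  fs <- rec$sampling_rate
  tt <- rec$t0 + (seq_along(x) - 1) / fs
  empty <- breath_series(numeric(0), numeric(0), numeric(0), numeric(0))
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("flat respiration signal: no breaths detected")
    return(empty)
  }
  up <- which(x[-length(x)] <= 0 & x[-1] > 0)
  down <- which(x[-length(x)] >= 0 & x[-1] < 0)
  if (length(up) < 2) {
    warning("no complete breath cycles found")
    return(empty)
  }
  peaks <- data.frame(idx = integer(0), trough_idx = integer(0))
  for (k in seq_len(length(up) - 1)) {
    seg <- up[k]:up[k + 1]
    p <- seg[which.max(x[seg])]
    # preceding trough: minimum since the previous up-crossing's predecessor
    prev <- if (k == 1) 1L else up[k - 1]
    tr_seg <- prev:up[k]
    tr <- tr_seg[which.min(x[tr_seg])]
    peaks <- rbind(peaks, data.frame(idx = p, trough_idx = tr))
  }
  amp <- x[peaks$idx] - x[peaks$trough_idx]
  floor_amp <- amp_floor_frac * stats::median(amp)
  keep <- amp >= floor_amp & amp > 0
  peaks <- peaks[keep, , drop = FALSE]
  amp <- amp[keep]
  if (!nrow(peaks)) {
    warning("no breaths above the amplitude floor")
    return(empty)
  }
  # enforce minimum breath duration: merge peaks closer than min_duration
  repeat {
    gaps <- diff(tt[peaks$idx])
    j <- which(gaps < min_duration)
    if (!length(j)) break
    j <- j[1]
    drop <- if (amp[j] >= amp[j + 1]) j + 1L else j
    peaks <- peaks[-drop, , drop = FALSE]
    amp <- amp[-drop]
  }
  pt <- tt[peaks$idx]
  rate <- c(NA_real_, 60 / diff(pt))
  breath_series(pt, tt[peaks$trough_idx], amp, rate)
}

#' Respiratory rate and amplitude time series
#'
#' Per-breath values interpolated onto a uniform grid; the rate at a grid
#' time is the instantaneous breaths/min implied by the enclosing
#' peak-to-peak interval, the amplitude that of the nearest breath
#' (linearly interpolated).
#'
#' @param breaths A [breath_series()] with >= 2 breaths.
#' @param step Grid step, seconds. Default 1.
#' @return A list of two [sliding_metric_series()]: `rate` (breaths/min) and
#'   `amplitude` (signal units).
#' @export
resp_series <- function(breaths, step = 1) {
  stopifnot(inherits(breaths, "breath_series"))
  if (length(breaths$peak_times) < 2)
    stop("need at least 2 breaths for a rate series")
  pt <- breaths$peak_times
  grid <- seq(ceiling(pt[1] / step) * step, pt[length(pt)], by = step)
  rate <- stats::approx(pt[-1], breaths$rate[-1], xout = grid, rule = 2)$y
  amp <- stats::approx(pt, breaths$amplitude, xout = grid, rule = 2)$y
  list(rate = sliding_metric_series(grid, rate, metric = "resp_rate",
                                    step = step),
       amplitude = sliding_metric_series(grid, amp, metric = "resp_amplitude",
                                         step = step))
}
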