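#' Construct an ECG recording
#'
#' A uniformly sampled single-channel ECG trace. Timestamps are implied by
#' `sampling_rate` and `t0`; sample `i` (0-based) sits at `t0 + i / sampling_rate`
#' seconds.
#'
#' @param samples Numeric vector of voltages (arbitrary units).
#' @param sampling_rate Sampling rate in Hz, > 0.
#' @param t0 Time offset of the first sample, seconds.
#' @param meta Optional named list of free-form metadata (subject id, channel, ...).
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, sampling_rate, t0 = 0, meta = list()) {
  stopifnot(is.numeric(samples), length(sampling_rate) == 1L, sampling_rate > 0)
  if (any(!is.finite(samples))) stop("ECG samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 t0 = as.numeric(t0), meta = meta),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Construct a respiration recording
#'
#' @param samples Numeric vector, respiration signal in arbitrary units.
#' @param sampling_rate Sampling rate in Hz, > 0.
#' @param t0 Time offset of the first sample, seconds.
#' @return An object of class `resp_recording`.
#' @export
resp_recording <- function(samples, sampling_rate, t0 = 0) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (any(!is.finite(samples))) stop("respiration samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 t0 = as.numeric(t0)),
            class = "resp_recording")
}

#' @export
print.resp_recording <- function(x, ...) {
  cat(sprintf("<resp_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Construct an R-peak series
#'
#' @param times Strictly increasing peak times, seconds.
#' @param corrected_flags Logical per peak; `TRUE` marks peaks inserted or
#'   moved by ectopic correction.
#' @param source `"detected"` or `"imported"`.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(times, corrected_flags = rep(FALSE, length(times)),
                         source = c("detected", "imported")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("peak times must be strictly increasing")
  if (length(corrected_flags) != length(times))
    stop("corrected_flags must match times in length")
  structure(list(times = times, corrected_flags = as.logical(corrected_flags),
                 source = source),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks (%s), %d corrected\n",
              length(x$times), x$source, sum(x$corrected_flags)))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' The substrate of every HRV metric: interbeat intervals in milliseconds with
#' the timestamp of the second beat of each pair.
#'
#' @param intervals Interbeat intervals in ms, all > 0.
#' @param times Strictly increasing timestamps in seconds, one per interval
#'   (the time of the later beat of the pair). If missing, times are
#'   accumulated from the intervals themselves.
#' @param quality_flags Character per interval: `"ok"`, `"suspect"` or
#'   `"excluded"`.
#' @param excluded Logical scalar: whole-series exclusion verdict (set by
#'   [screen_quality()] or [correct_ectopic()] when the series is unsalvageable).
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, times = NULL,
                      quality_flags = rep("ok", length(intervals)),
                      excluded = FALSE) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("RR intervals must be finite and positive")
  if (is.null(times)) times <- cumsum(intervals) / 1000
  times <- as.numeric(times)
  if (length(times) != length(intervals))
    stop("times must match intervals in length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("interval times must be strictly increasing")
  if (length(quality_flags) != length(intervals))
    stop("quality_flags must match intervals in length")
  if (!all(quality_flags %in% c("ok", "suspect", "excluded")))
    stop("quality_flags must be 'ok', 'suspect' or 'excluded'")
  structure(list(intervals = intervals, times = times,
                 quality_flags = as.character(quality_flags),
                 excluded = isTRUE(excluded)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals over %.1f s, mean RR %.0f ms, %d flagged%s\n",
    length(x$intervals), diff(range(x$times)), mean(x$intervals),
    sum(x$quality_flags != "ok"),
    if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Construct a sliding-metric series
#'
#' Uniformly stepped time series of a windowed metric (RMSSD, HR, HRV
#' amplitude, respiratory rate/amplitude) with coverage information.
#'
#' @param times Uniform grid times, seconds.
#' @param values Metric values (ms, bpm, breaths/min, ...).
#' @param n_beats Number of intervals (or breaths) contributing to each point.
#' @param valid Logical per point; `FALSE` where coverage was insufficient.
#' @param metric Metric name, e.g. `"rmssd"`.
#' @param step Grid step, seconds.
#' @return An object of class `sliding_metric_series`.
#' @export
sliding_metric_series <- function(times, values, n_beats = rep(NA_integer_,
                                  length(times)),
                                  valid = rep(TRUE, length(times)),
                                  metric = "metric", step = NA_real_) {
  stopifnot(length(values) == length(times), length(valid) == length(times))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 n_beats = as.integer(n_beats), valid = as.logical(valid),
                 metric = metric, step = step),
            class = "sliding_metric_series")
}

#' @export
print.sliding_metric_series <- function(x, ...) {
  cat(sprintf("<sliding_metric_series> '%s': %d points, step %g s, %d valid\n",
              x$metric, length(x$times), x$step, sum(x$valid)))
  invisible(x)
}

#' @export
as.data.frame.sliding_metric_series <- function(x, ...) {
  data.frame(time_s = x$times, metric = x$metric, value = x$values,
             valid = x$valid)
}

#' Construct segment windows
#'
#' Labeled time windows (VR chapters, baseline, post-injection, ...) used for
#' window averaging of metric time series.
#'
#' @param label Character labels.
#' @param start,end Window bounds in seconds, `start < end` elementwise.
#' @return A data frame of class `segment_windows` with columns
#'   `label`, `start`, `end`.
#' @export
segment_windows <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("each window must satisfy start < end")
  structure(data.frame(label = as.character(label), start = as.numeric(start),
                       end = as.numeric(end), stringsAsFactors = FALSE),
            class = c("segment_windows", "data.frame"))
}
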