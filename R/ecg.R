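# ECG chain: band-pass filter -> R-peak detection -> RR intervals ->
# ectopic correction -> quality screening.

#' Zero-phase FIR band-pass filter for ECG
#'
#' Applies a linear-phase FIR band-pass (Hamming-windowed, as in standard
#' acquisition software) forward and backward so the net filter is zero-phase:
#' R-peak times are not systematically shifted, which matters because the
#' timestamps feed every downstream metric.
#'
#' @param rec An [ecg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < sampling_rate / 2`.
#' @param taps Number of FIR taps (filter length), >= 3. Default 120.
#' @return A filtered [ecg_recording()] of the same length and rate.
#' @export
bandpass_ecg <- function(rec, low = 0.5, high = 30, taps = 120) {
  stopifnot(inherits(rec, "ecg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  if (taps < 3) stop("taps must be >= 3")
  n <- length(rec$samples)
  if (n <= 3 * (taps + 1))
    stop("signal shorter than filter transient; need > 3 * (taps + 1) samples")
  b <- signal::fir1(taps, c(low, high) / nyq, type = "pass")
  # a short FIR leaves residual DC; remove the mean first so the stop band
  # at 0 Hz is exact and edge transients stay small
  y <- signal::filtfilt(signal::Ma(b), rec$samples - mean(rec$samples))
  ecg_recording(y, rec$sampling_rate, rec$t0, rec$meta)
}

#' Detect R peaks in a (filtered) ECG trace
#'
#' A Pan-Tompkins-style detector: the trace is restricted to the 5-15 Hz
#' QRS energy band, differentiated, squared and integrated over a 150 ms
#' moving window; candidate energy peaks are screened by adaptive signal and
#' noise running levels, with a searchback pass that rescues sub-threshold
#' beats inside implausibly long gaps (> 1.66 x the running RR average) at
#' half threshold. Each accepted detection is refined to the local maximum
#' of the (lightly smoothed) input trace. A 250 ms refractory period
#' suppresses double detections.
#'
#' @param rec An [ecg_recording()], ideally already band-pass filtered.
#' @param refractory Minimum peak spacing, seconds.
#' @param threshold_frac Position of the detection threshold between the
#'   running noise and signal energy levels.
#' @return An [rpeak_series()]; empty (with a warning) on flat input.
#' @export
detect_r_peaks <- function(rec, refractory = 0.25, threshold_frac = 0.25) {
  stopifnot(inherits(rec, "ecg_recording"))
  fs <- rec$sampling_rate
  x <- rec$samples
  if (length(x) < 2 * fs)
    stop("need at least 2 s of ECG for peak detection")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("flat ECG signal: no peaks detected")
    return(rpeak_series(numeric(0), logical(0), source = "detected"))
  }
  # QRS band -> derivative -> square -> moving-window integration (150 ms)
  bw <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bw, x)
  d <- c(0, diff(xf)) * fs
  e <- d^2
  w <- max(3L, round(0.15 * fs))
  integ <- stats::filter(e, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # candidate peaks of the integrated energy, >= 200 ms apart
  n <- length(integ)
  i <- 2:(n - 1)
  cand <- i[integ[i] > integ[i - 1] & integ[i] >= integ[i + 1]]
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) {
    warning("no QRS-like activity found")
    return(rpeak_series(numeric(0), logical(0), source = "detected"))
  }
  min_sep <- round(0.2 * fs)
  if (length(cand) > 1) {
    keep <- rep(TRUE, length(cand))
    last <- 1L
    for (k in 2:length(cand)) {
      if (cand[k] - cand[last] < min_sep) {
        if (integ[cand[k]] > integ[cand[last]]) { keep[last] <- FALSE
                                                  last <- k }
        else keep[k] <- FALSE
      } else last <- k
    }
    cand <- cand[keep]
  }
  # adaptive signal / noise levels with long-gap searchback
  spk <- stats::quantile(integ[cand], 0.95, names = FALSE)
  npk <- stats::median(integ)
  acc <- integer(0)
  for (ci in cand) {
    thr <- npk + threshold_frac * (spk - npk)
    if (integ[ci] > thr) {
      if (length(acc) >= 2) {
        rr_avg <- mean(diff(utils::tail(acc, 9)))
        if (ci - utils::tail(acc, 1) > 1.66 * rr_avg) {
          inb <- cand[cand > utils::tail(acc, 1) + min_sep &
                        cand < ci - min_sep]
          if (length(inb)) {
            bi <- inb[which.max(integ[inb])]
            if (integ[bi] > thr / 2) {
              acc <- c(acc, bi)
              spk <- 0.25 * integ[bi] + 0.75 * spk
            }
          }
        }
      }
      acc <- c(acc, ci)
      spk <- 0.125 * integ[ci] + 0.875 * spk
    } else {
      npk <- 0.125 * integ[ci] + 0.875 * npk
    }
  }
  if (!length(acc)) {
    warning("no QRS-like activity above threshold")
    return(rpeak_series(numeric(0), logical(0), source = "detected"))
  }
  # refine each detection to the local maximum of the smoothed trace
  sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  half <- round(0.1 * fs)
  peaks <- vapply(acc, function(c0) {
    lo <- max(1L, c0 - half); hi <- min(length(x), c0 + half)
    lo + which.max(sm[lo:hi]) - 1L
  }, numeric(1))
  peaks <- sort(unique(peaks))
  # refractory: keep the larger of any pair closer than `refractory`
  repeat {
    gaps <- diff(peaks) / fs
    j <- which(gaps < refractory)
    if (!length(j)) break
    j <- j[1]
    drop <- if (sm[peaks[j]] >= sm[peaks[j + 1]]) j + 1L else j
    peaks <- peaks[-drop]
  }
  rpeak_series(rec$t0 + (peaks - 1L) / fs,
               rep(FALSE, length(peaks)), source = "detected")
}

#' RR intervals from an R-peak series
#'
#' First differences of the peak times, in ms; each interval is stamped with
#' the time of its second beat.
#'
#' @param peaks An [rpeak_series()] with >= 2 peaks.
#' @return An [rr_series()].
#' @export
rr_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$times) < 2)
    stop("need at least 2 peaks to form an interval")
  rr_series(diff(peaks$times) * 1000, peaks$times[-1])
}

#' Correct ectopic, missed and extra beats in an RR series
#'
#' A dRR-threshold procedure in the style of the Kubios artifact corrector:
#' each interval is compared with a local running median; intervals deviating
#' beyond a threshold (the larger of a relative bound and a
#' quartile-deviation-scaled bound on successive differences) are classified
#' as missed (interval about twice the local median: a beat is inserted),
#' extra (two short intervals summing to the local median: the spurious beat
#' is deleted), or ectopic (premature beat: the beat is moved to the position
#' interpolated from neighboring accepted intervals). Corrections operate on
#' beat times, so total record duration is preserved and the interval/time
#' identity holds everywhere.
#'
#' @param rr An [rr_series()] with >= 10 intervals.
#' @param rel_thresh Relative deviation bound (fraction of the local median).
#' @param qd_scale Multiplier on the local quartile deviation of successive
#'   differences entering the adaptive part of the threshold.
#' @param max_pass Maximum correction sweeps.
#' @return An [rr_series()]; corrected intervals are flagged `"suspect"`.
#'   If more than half of the intervals are initially flagged, the series is
#'   returned unchanged with `excluded = TRUE` (unsalvageable).
#' @export
correct_ectopic <- function(rr, rel_thresh = 0.2, qd_scale = 4.5,
                            max_pass = 25) {
  stopifnot(inherits(rr, "rr_series"))
  n0 <- length(rr$intervals)
  if (n0 < 10) stop("need >= 10 intervals for ectopic correction")
  bt <- c(rr$times[1] - rr$intervals[1] / 1000, rr$times)
  touched <- rep(FALSE, length(bt))

  thresholds <- function(x) {
    med <- stats::runmed(x, k = min(11L, 2L * (length(x) %/% 2L) - 1L),
                         endrule = "median")
    drr <- diff(x)
    qd <- if (length(drr) >= 4)
      diff(stats::quantile(drr, c(0.25, 0.75), names = FALSE)) / 2 else 0
    list(med = med, thr = pmax(rel_thresh * med, qd_scale * qd))
  }

  # unsalvageability check on the relative criterion alone: under heavy
  # corruption the quartile-deviation term inflates and would mask it
  x <- diff(bt) * 1000
  th <- thresholds(x)
  if (mean(abs(x - th$med) > rel_thresh * th$med) > 0.5) {
    rr$excluded <- TRUE
    rr$quality_flags <- rep("excluded", n0)
    return(rr)
  }

  for (pass in seq_len(max_pass)) {
    x <- diff(bt) * 1000
    n <- length(x)
    th <- thresholds(x)
    dev <- x - th$med
    bad <- which(abs(dev) > th$thr)
    # lone long intervals below the missed-beat ratio are kept (suspect only)
    actionable <- bad[x[bad] > 1.6 * th$med[bad] | x[bad] < th$med[bad]]
    if (!length(actionable)) break
    i <- actionable[1]
    med_i <- th$med[i]
    if (x[i] > 1.6 * med_i) {
      # missed beat(s): insert k evenly spaced beats
      k <- max(1L, round(x[i] / med_i) - 1L)
      new_t <- bt[i] + seq_len(k) * (bt[i + 1] - bt[i]) / (k + 1)
      o <- order(c(bt, new_t))
      touched <- c(touched, rep(TRUE, k))[o]
      bt <- c(bt, new_t)[o]
    } else if (i < n && abs(x[i] + x[i + 1] - th$med[i]) <= th$thr[i]) {
      # extra (spurious) detection: delete the middle beat
      bt <- bt[-(i + 1)]
      touched <- touched[-(i + 1)]
      touched[i] <- TRUE
    } else if (i == 1) {
      # aberrant leading interval: drop the first beat
      bt <- bt[-1]; touched <- touched[-1]; touched[1] <- TRUE
    } else if (i == n) {
      # aberrant trailing interval: drop the last beat
      bt <- bt[-(n + 1)]; touched <- touched[-(n + 1)]
      touched[length(touched)] <- TRUE
    } else {
      # ectopic premature beat: move beat i+1 to the position interpolated
      # from neighboring accepted intervals (cubic through nearby values)
      nb <- setdiff(seq(max(1, i - 3), min(n, i + 4)), c(i, i + 1))
      est <- if (length(nb) >= 2)
        stats::spline(nb, x[nb], xout = i)$y else med_i
      gap <- bt[i + 2] - bt[i]
      pos <- bt[i] + est / 1000
      pos <- min(max(pos, bt[i] + 0.1 * gap), bt[i] + 0.9 * gap)
      bt[i + 1] <- pos
      touched[i + 1] <- TRUE
    }
  }

  x <- diff(bt) * 1000
  flags <- rep("ok", length(x))
  corr <- touched[-1] | touched[-length(touched)]
  flags[corr] <- "suspect"
  out <- rr_series(x, bt[-1], flags)
  out
}

#' Screen an RR series for residual detection quality
#'
#' Tiles the record into fixed windows and marks a window poor when the
#' fraction of corrected or out-of-physiologic-range intervals inside it
#' exceeds `window_frac`. The whole series is marked excluded when the
#' fraction of poor windows exceeds `series_frac`.
#'
#' @param rr An [rr_series()] (typically output of [correct_ectopic()]).
#' @param window Window length, seconds. Default 30 (aligned with the RMSSD
#'   analysis window).
#' @param window_frac Per-window poor-interval fraction threshold.
#' @param series_frac Poor-window fraction above which the series is excluded.
#' @param bounds Physiologic interval bounds, ms.
#' @return A list: `rr` (flags updated, `excluded` set when warranted),
#'   `report` (per-window data frame with verdicts) and `verdict`
#'   (`"keep"` or `"exclude"`).
#' @export
screen_quality <- function(rr, window = 30, window_frac = 0.2,
                           series_frac = 0.1, bounds = c(250, 3000)) {
  stopifnot(inherits(rr, "rr_series"), window > 0)
  poor_int <- rr$quality_flags != "ok" |
    rr$intervals < bounds[1] | rr$intervals > bounds[2]
  t0 <- rr$times[1] - rr$intervals[1] / 1000
  starts <- seq(t0, max(rr$times), by = window)
  report <- do.call(rbind, lapply(starts, function(s) {
    in_w <- rr$times > s & rr$times <= s + window
    n <- sum(in_w)
    frac <- if (n) mean(poor_int[in_w]) else 0
    data.frame(start = s, end = s + window, n_intervals = n,
               frac_poor = frac, bad = n > 0 & frac > window_frac)
  }))
  bad_frac <- mean(report$bad)
  verdict <- if (bad_frac > series_frac) "exclude" else "keep"
  rr$excluded <- rr$excluded || verdict == "exclude"
  if (verdict == "exclude") {
    rr$quality_flags[poor_int] <- "excluded"
  }
  list(rr = rr, report = report, verdict = verdict, bad_frac = bad_frac)
}
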