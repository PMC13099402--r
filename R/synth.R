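# Ground-truth synthetic generators. Every generator is deterministic under a
# fixed seed and returns a `truth` record sufficient to score any downstream
# recovery without re-deriving generator internals.

local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) return(invisible(NULL))
  assign(".Random.seed", old, envir = globalenv())
}

#' Specification for a synthetic RR-interval series
#'
#' @param duration Total duration, seconds.
#' @param base_rr Mean interbeat interval, ms.
#' @param modulations List of `list(freq, amp, phase)` entries: sinusoidal
#'   interval modulations with frequency in Hz (evaluated in continuous time at
#'   the running beat time, so frequencies have physical units), amplitude in
#'   ms and phase in radians.
#' @param jitter_sd White beat-to-beat noise sd, ms.
#' @param ectopic_rate Per-beat probability of an ectopic event (the affected
#'   interval is split into an early 0.5x beat followed by a 1.5x compensatory
#'   pause).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `rr_gen_spec`.
#' @export
rr_gen_spec <- function(duration = 300, base_rr = 800,
                        modulations = list(), jitter_sd = 0,
                        ectopic_rate = 0, seed = NULL) {
  amp_sum <- if (length(modulations))
    sum(vapply(modulations, function(m) m$amp, 0)) else 0
  if (base_rr <= amp_sum + 5 * jitter_sd)
    stop("base_rr must exceed total modulation amplitude + 5 * jitter_sd")
  structure(list(duration = duration, base_rr = base_rr,
                 modulations = modulations, jitter_sd = jitter_sd,
                 ectopic_rate = ectopic_rate, seed = seed),
            class = "rr_gen_spec")
}

mod_value <- function(modulations, t) {
  if (!length(modulations)) return(0)
  sum(vapply(modulations,
             function(m) m$amp * sin(2 * pi * m$freq * t +
                                       (m$phase %||% 0)), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic RR-interval series
#'
#' Beat times are generated iteratively: the next interval equals
#' `base_rr` plus the sum of the modulation terms evaluated at the current
#' beat time plus white jitter. Ectopic events replace an interval by a
#' premature 0.5x beat followed by a 1.5x compensatory pause, the classic
#' short-long signature an ectopic-beat corrector must repair.
#'
#' @param spec An [rr_gen_spec()].
#' @return A list with elements `rr` (an [rr_series()]) and `truth`
#'   (clean intervals, clean beat times, indices of ectopic-shortened
#'   intervals, and the spec).
#' @export
synth_rr <- function(spec) {
  stopifnot(inherits(spec, "rr_gen_spec"))
  old <- local_seed(spec$seed); on.exit(restore_seed(old))
  t <- 0
  clean <- numeric(0)
  repeat {
    rr <- spec$base_rr + mod_value(spec$modulations, t) +
      (if (spec$jitter_sd > 0) stats::rnorm(1, 0, spec$jitter_sd) else 0)
    rr <- max(rr, 200)                       # hard physiological floor
    if (t + rr / 1000 > spec$duration) break
    clean <- c(clean, rr)
    t <- t + rr / 1000
  }
  intervals <- clean
  ectopic_idx <- integer(0)
  if (spec$ectopic_rate > 0 && length(clean) > 2) {
    hit <- which(stats::runif(length(clean) - 1) < spec$ectopic_rate)
    # avoid adjacent hits corrupting each other's compensatory pause
    hit <- hit[c(TRUE, diff(hit) > 1)]
    out <- list()
    i <- 1
    while (i <= length(clean)) {
      if (i %in% hit) {
        out[[length(out) + 1]] <- 0.5 * clean[i]
        ectopic_idx <- c(ectopic_idx, length(out))
        out[[length(out) + 1]] <- 0.5 * clean[i] + clean[i + 1]
        i <- i + 2
      } else {
        out[[length(out) + 1]] <- clean[i]
        i <- i + 1
      }
    }
    intervals <- unlist(out)
  }
  rr <- rr_series(intervals)
  list(rr = rr,
       truth = list(clean_intervals = clean,
                    clean_times = cumsum(clean) / 1000,
                    ectopic_idx = ectopic_idx, spec = spec))
}

#' Render an RR-interval series as a synthetic ECG trace
#'
#' Places a stereotyped QRS-like waveform (narrow R spike flanked by small Q
#' and S deflections) at each beat time, so that the true R-peak times of the
#' output equal the input beat times exactly (to sample resolution).
#'
#' @param rr An [rr_series()]; beat times are `c(t1 - rr1/1000, times)`.
#' @param rate Sampling rate in Hz, >= 100.
#' @param noise_sd Additive white Gaussian noise sd, in units of the R-wave
#'   amplitude (1.0). `noise_sd = 10^(-snr_db/20)` gives a chosen SNR.
#' @return A list with elements `ecg` (an [ecg_recording()]) and `truth`
#'   (true R-peak times in seconds).
#' @export
synth_ecg <- function(rr, rate = 180, noise_sd = 0) {
  stopifnot(inherits(rr, "rr_series"))
  if (rate < 100) stop("rate must be >= 100 Hz")
  if (!length(rr$intervals)) stop("empty RR series")
  beat_times <- c(rr$times[1] - rr$intervals[1] / 1000, rr$times)
  beat_times <- beat_times - min(beat_times) + 0.5
  dur <- max(beat_times) + 0.5
  n <- ceiling(dur * rate)
  tt <- (0:(n - 1)) / rate
  x <- numeric(n)
  # QRS template: R spike sigma 12 ms, Q/S dips at +/-35 ms
  for (bt in beat_times) {
    idx <- which(abs(tt - bt) < 0.12)
    d <- tt[idx] - bt
    x[idx] <- x[idx] + exp(-(d / 0.012)^2) -
      0.25 * exp(-((d + 0.035) / 0.02)^2) -
      0.25 * exp(-((d - 0.035) / 0.02)^2)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  list(ecg = ecg_recording(x, rate),
       truth = list(r_times = beat_times))
}

#' Generate a synthetic respiration signal
#'
#' A sinusoid with time-varying instantaneous rate and amplitude (phase is
#' integrated, so rate changes are smooth) plus optional white noise.
#'
#' @param duration Seconds.
#' @param rate_profile Either a single rate in breaths/min (2-40) or a
#'   function of time (seconds) returning breaths/min.
#' @param amplitude_profile A single amplitude (signal units) or a function of
#'   time.
#' @param sampling_rate Hz.
#' @param noise_sd White noise sd, signal units.
#' @param seed Integer seed or `NULL`.
#' @return A list with elements `resp` (a [resp_recording()]) and `truth`
#'   (instantaneous rate/amplitude at each sample).
#' @export
synth_resp <- function(duration = 60, rate_profile = 15,
                       amplitude_profile = 1, sampling_rate = 180,
                       noise_sd = 0, seed = NULL) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  rate_fun <- if (is.function(rate_profile)) rate_profile
              else function(t) rep(rate_profile, length(t))
  amp_fun <- if (is.function(amplitude_profile)) amplitude_profile
             else function(t) rep(amplitude_profile, length(t))
  n <- ceiling(duration * sampling_rate)
  tt <- (0:(n - 1)) / sampling_rate
  rates <- rate_fun(tt)
  if (any(rates < 0) || any(rates > 40))
    stop("rate_profile must stay within 0-40 breaths/min")
  phase <- cumsum(2 * pi * rates / 60) / sampling_rate
  amps <- amp_fun(tt)
  x <- amps * sin(phase)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  list(resp = resp_recording(x, sampling_rate),
       truth = list(times = tt, rate = rates, amplitude = amps))
}

#' Specification for a synthetic participant cohort
#'
#' The cohort embodies the hinge-shaped rating-to-HRV-amplitude relationship
#' the segmented-regression analysis assumes: amplitude is flat below a known
#' breakpoint and rises linearly above it, on top of covariate effects and
#' noise.
#'
#' @param n Number of participants (>= 10).
#' @param breakpoint Breakpoint on the rating scale.
#' @param slope_above Amplitude increase per rating unit above the breakpoint
#'   (normalized amplitude units, matching a 0-1 min-max scale).
#' @param noise_sd Residual sd of normalized amplitude.
#' @param rating_range Length-2 numeric, uniform sampling range of ratings.
#' @param baseline Amplitude intercept (normalized units).
#' @param covariate_effects Named numeric: linear effects of `age` (per year),
#'   `gender` (indicator) and `bmi` (per kg/m2) on normalized amplitude.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 44, breakpoint = 7.0, slope_above = 0.0218,
                        noise_sd = 0.02, rating_range = c(0, 10),
                        baseline = 0.25,
                        covariate_effects = c(age = 0.002, gender = 0.01,
                                              bmi = 0.003),
                        seed = NULL) {
  if (n < 10) stop("cohort needs n >= 10")
  if (breakpoint < rating_range[1] || breakpoint > rating_range[2])
    stop("breakpoint must lie within rating_range")
  structure(list(n = n, breakpoint = breakpoint, slope_above = slope_above,
                 noise_sd = noise_sd, rating_range = rating_range,
                 baseline = baseline, covariate_effects = covariate_effects,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic participant cohort
#'
#' Ratings are uniform over `rating_range`; HRV amplitude follows
#' `baseline + slope_above * max(0, rating - breakpoint)` plus covariate
#' effects and Gaussian noise. Covariates: age ~ N(27, 10) truncated at
#' 18-65, gender ~ Bernoulli(0.6), BMI ~ N(23, 3) truncated at 16-40.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `participants` (a data frame with columns
#'   `id`, `group`, `age`, `gender`, `bmi`, `ego_reduction`, `hrv_amplitude`,
#'   `resp_amplitude`) and `truth` (all generating coefficients).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- local_seed(spec$seed); on.exit(restore_seed(old))
  n <- spec$n
  age <- pmin(pmax(stats::rnorm(n, 27, 10), 18), 65)
  gender <- stats::rbinom(n, 1, 0.6)
  bmi <- pmin(pmax(stats::rnorm(n, 23, 3), 16), 40)
  rating <- stats::runif(n, spec$rating_range[1], spec$rating_range[2])
  ce <- spec$covariate_effects
  amp <- spec$baseline +
    spec$slope_above * pmax(0, rating - spec$breakpoint) +
    ce[["age"]] * (age - mean(age)) + ce[["gender"]] * gender +
    ce[["bmi"]] * (bmi - mean(bmi)) +
    stats::rnorm(n, 0, spec$noise_sd)
  # respiratory amplitude weakly tracks HRV amplitude, as real cohorts show
  resp_amp <- 0.3 * amp + stats::rnorm(n, 0, 0.05)
  participants <- data.frame(
    id = sprintf("P%03d", seq_len(n)), group = "VR",
    age = age, gender = gender, bmi = bmi,
    ego_reduction = rating, hrv_amplitude = amp, resp_amplitude = resp_amp,
    stringsAsFactors = FALSE)
  list(participants = participants,
       truth = list(spec = spec, breakpoint = spec$breakpoint,
                    slope_above = spec$slope_above,
                    covariate_effects = ce))
}

#' Default three-phase session profile
#'
#' Baseline (moderate slow modulation), sympathetic surge (short intervals,
#' suppressed modulation) and vagal rebound (elevated modulation amplitude) --
#' the qualitative time course expected around a short-acting pharmacological
#' challenge: an 8-minute baseline followed by 20 minutes post-injection.
#'
#' @param baseline_min,surge_min,rebound_min Phase durations, minutes.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `session_profile`: ordered phases, each with a
#'   label, duration and RR-generation overrides.
#' @export
session_profile <- function(baseline_min = 8, surge_min = 3,
                            rebound_min = 17, seed = NULL) {
  phases <- list(
    list(label = "baseline", duration = baseline_min * 60,
         base_rr = 800, mod_amp = 50, mod_freq = 0.1, jitter_sd = 10),
    list(label = "surge", duration = surge_min * 60,
         base_rr = 620, mod_amp = 12, mod_freq = 0.1, jitter_sd = 6),
    list(label = "rebound", duration = rebound_min * 60,
         base_rr = 780, mod_amp = 110, mod_freq = 0.1, jitter_sd = 10))
  structure(list(phases = phases, seed = seed), class = "session_profile")
}

#' Generate a synthetic multi-phase session RR series
#'
#' Concatenates per-phase RR generators (see [session_profile()]); phase
#' boundaries are recorded as truth so window-based analyses can be scored.
#'
#' @param profile A [session_profile()].
#' @return A list with elements `rr` (an [rr_series()] spanning all phases)
#'   and `truth` (phase labels with start/end times in seconds, and the
#'   injection time = end of the first phase).
#' @export
synth_session <- function(profile) {
  stopifnot(inherits(profile, "session_profile"))
  old <- local_seed(profile$seed); on.exit(restore_seed(old))
  intervals <- numeric(0)
  t_off <- 0
  bounds <- data.frame(label = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  for (ph in profile$phases) {
    spec <- rr_gen_spec(duration = ph$duration, base_rr = ph$base_rr,
                        modulations = list(list(freq = ph$mod_freq,
                                                amp = ph$mod_amp, phase = 0)),
                        jitter_sd = ph$jitter_sd, seed = NULL)
    g <- synth_rr(spec)
    intervals <- c(intervals, g$rr$intervals)
    bounds <- rbind(bounds, data.frame(label = ph$label, start = t_off,
                                       end = t_off + ph$duration,
                                       stringsAsFactors = FALSE))
    t_off <- t_off + ph$duration
  }
  rr <- rr_series(intervals)
  list(rr = rr,
       truth = list(phases = bounds,
                    injection_time = bounds$end[1]))
}
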