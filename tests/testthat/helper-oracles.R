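# Brute-force oracles kept deliberately independent of the implementation
# paths they check.

# single-frequency amplitude of a signal via direct DFT projection
dft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  tt <- (0:(n - 1)) / fs
  2 * Mod(sum(x * exp(-2i * pi * freq * tt))) / n
}

# direct-formula RMSSD over intervals whose times fall in [lo, hi]
oracle_rmssd <- function(intervals, times, lo, hi) {
  sel <- times > lo & times <= hi
  x <- intervals[sel]
  if (length(x) < 2) return(NA_real_)
  sqrt(mean(diff(x)^2))
}

# neighbor-comparison local extrema (loop form)
oracle_extrema <- function(x) {
  mx <- integer(0); mn <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] <= x[i + 1]) mn <- c(mn, i)
  }
  list(max_idx = mx, min_idx = mn)
}

# brute-force envelope: moving median over extrema + linear interpolation
oracle_envelope_amplitude <- function(x, tt, window = 5) {
  ext <- oracle_extrema(x)
  med_at <- function(idx) {
    v <- x[idx]
    half <- (window - 1) %/% 2
    sapply(seq_along(v), function(j) {
      k <- min(half, j - 1, length(v) - j)
      median(v[(j - k):(j + k)])
    })
  }
  up <- approx(tt[ext$max_idx], med_at(ext$max_idx), xout = tt, rule = 2)$y
  lo <- approx(tt[ext$min_idx], med_at(ext$min_idx), xout = tt, rule = 2)$y
  pmax(up - lo, 0)
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# fraction of truth beats matched by a detection within tol seconds
match_rate <- function(truth, detected, tol = 0.05) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(t) any(abs(detected - t) < tol), TRUE))
}
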