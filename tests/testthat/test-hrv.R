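test_that("local extrema follow the neighbor rule with first-point plateaus", {
  ext <- local_extrema(c(800, 900, 800, 900, 800))
  expect_equal(ext$max_idx, c(2L, 4L))
  expect_equal(ext$min_idx, 3L)

  const <- local_extrema(rep(800, 10))
  expect_length(const$max_idx, 0)
  expect_length(const$min_idx, 0)

  # plateau bounded by smaller neighbors counts once, at its first point
  plat <- local_extrema(c(1, 5, 5, 5, 1))
  expect_equal(plat$max_idx, 2L)

  expect_error(local_extrema(c(1, 2)), "3 points")

  set.seed(21)
  x <- 800 + 100 * sin(2 * pi * (1:500) / 23) + rnorm(500, 0, 15)
  expect_equal(local_extrema(x), oracle_extrema(x))
})

test_that("envelope amplitude is exact on alternating and constant series", {
  alt <- rr_series(rep(c(800, 900), 8))
  e <- envelope(alt)
  expect_equal(unique(e$amplitude), 100)
  expect_true(all(e$upper == 900) && all(e$lower == 800))

  e0 <- envelope(rr_series(rep(800, 12)))
  expect_equal(max(e0$amplitude), 0)
})

test_that("envelope tracks a sinusoidal modulation within 10%", {
  i <- 0:399
  rr <- rr_series(800 + 100 * sin(2 * pi * i / 20))
  e <- envelope(rr)
  interior <- 30:370
  expect_true(all(abs(e$amplitude[interior] - 200) <= 20))
  expect_equal(e$amplitude,
               oracle_envelope_amplitude(rr$intervals, rr$times),
               tolerance = 1e-12)
})

test_that("median envelope rejects an isolated outlier", {
  x <- rep(c(800, 900), 10)
  x[9] <- 1500   # odd index: replaces a maximum-position beat
  rr <- rr_series(x)
  e <- envelope(rr)
  expect_equal(e$amplitude,
               oracle_envelope_amplitude(x, rr$times), tolerance = 1e-12)
  # interior amplitude unchanged: a 5-point median absorbs one outlier
  clean_amp <- envelope(rr_series(rep(c(800, 900), 10)))$amplitude
  interior <- 5:15
  expect_equal(e$amplitude[interior], clean_amp[interior])
})

test_that("envelope is translation invariant and scale equivariant", {
  set.seed(22)
  base <- 800 + 80 * sin(2 * pi * (1:300) / 18) + rnorm(300, 0, 10)
  rr <- rr_series(base)
  amp <- envelope(rr)$amplitude
  shifted <- envelope(rr_series(base + 250, rr$times))$amplitude
  expect_equal(shifted, amp, tolerance = 1e-9)
  scaled <- envelope(rr_series(1.7 * base, rr$times))$amplitude
  expect_equal(scaled, 1.7 * amp, tolerance = 1e-9)
})

test_that("resampled amplitude agrees with beat-time amplitude", {
  alt <- rr_series(rep(c(800, 900), 20))
  ts <- hrv_amplitude_timeseries(alt)
  expect_true(all(abs(ts$values - 100) < 1e-9))
  expect_equal(unique(round(diff(ts$times), 9)), 1)

  g <- synth_rr(rr_gen_spec(duration = 300, base_rr = 800,
                            modulations = list(list(freq = 0.05, amp = 80,
                                                    phase = 0)),
                            jitter_sd = 5, seed = 23))
  env <- envelope(g$rr)
  ts2 <- hrv_amplitude_timeseries(g$rr)
  # each grid value must lie between the bracketing beat-time values
  for (k in seq(10, length(ts2$times) - 10, by = 17)) {
    t <- ts2$times[k]
    j <- max(which(env$times <= t))
    lohi <- range(env$amplitude[j:(j + 1)])
    expect_gte(ts2$values[k], lohi[1] - 1e-9)
    expect_lte(ts2$values[k], lohi[2] + 1e-9)
  }
})

test_that("sliding RMSSD matches the direct-formula oracle", {
  const <- sliding_rmssd(rr_series(rep(800, 100)))
  expect_true(all(const$values[const$valid] == 0))

  alt <- sliding_rmssd(rr_series(rep(c(800, 810), 50)))
  expect_true(all(abs(alt$values[alt$valid] - 10) < 1e-9))

  set.seed(24)
  rr <- rr_series(runif(200, 600, 1000))
  out <- sliding_rmssd(rr)
  for (k in which(out$valid)) {
    expect_equal(out$values[k],
                 oracle_rmssd(rr$intervals, rr$times,
                              out$times[k] - 15, out$times[k] + 15))
  }
})

test_that("sliding HR matches 60000 / mean RR", {
  expect_true(all(abs(sliding_hr(rr_series(rep(1000, 100)))$values - 60)
                  < 1e-9, na.rm = TRUE))
  expect_true(all(abs(sliding_hr(rr_series(rep(800, 100)))$values - 75)
                  < 1e-9, na.rm = TRUE))
  set.seed(25)
  rr <- rr_series(runif(150, 600, 1000))
  out <- sliding_hr(rr, window = 30, step = 1)
  for (k in which(out$valid)) {
    sel <- rr$times > out$times[k] - 15 & rr$times <= out$times[k] + 15
    expect_equal(out$values[k], 60000 / mean(rr$intervals[sel]))
  }
})

test_that("window averaging aggregates labeled segments correctly", {
  s <- sliding_metric_series(0:119, c(rep(50, 60), rep(150, 60)),
                             metric = "m", step = 1)
  w <- segment_windows(c("A", "B"), c(0, 60), c(60, 120))
  out <- window_average(s, w, aggregates = list(AB = c("A", "B")))
  expect_equal(out$mean[out$label == "A"], 50)
  expect_equal(out$mean[out$label == "B"], 150)
  expect_equal(out$mean[out$label == "AB"], 100)

  # brute-force masked-mean oracle on random data
  set.seed(26)
  vals <- runif(200)
  valid <- runif(200) > 0.1
  s2 <- sliding_metric_series(0:199, vals, valid = valid, metric = "m",
                              step = 1)
  w2 <- segment_windows(c("w1", "w2", "w3"), c(3, 50.5, 120),
                        c(40, 99, 180.5))
  out2 <- window_average(s2, w2)
  for (k in 1:3) {
    sel <- s2$times >= w2$start[k] & s2$times < w2$end[k] & valid
    expect_equal(out2$mean[k], mean(vals[sel]))
  }
})

test_that("surge-rebound sessions show elevated post-acute amplitude", {
  for (seed in 1:3) {
    sess <- synth_session(session_profile(seed = seed))
    ts <- hrv_amplitude_timeseries(sess$rr)
    inj <- sess$truth$injection_time
    w <- segment_windows(c("acute", "post"),
                         c(inj, inj + 4 * 60),
                         c(inj + 3 * 60, inj + 20 * 60))
    out <- window_average(ts, w)
    expect_gt(out$mean[out$label == "post"],
              out$mean[out$label == "acute"])
  }
})
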