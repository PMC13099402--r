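test_that("band-pass rejects DC, preserves passband, attenuates stopband", {
  fs <- 180
  n <- 30 * fs
  tt <- (0:(n - 1)) / fs
  trim <- (2 * fs):(n - 2 * fs)  # discard filter transients

  dc <- bandpass_ecg(ecg_recording(rep(1, n), fs))
  expect_lt(max(abs(dc$samples[trim])), 1e-3)

  for (f in c(5, 10, 20)) {
    rec <- ecg_recording(sin(2 * pi * f * tt), fs)
    out <- bandpass_ecg(rec)
    gain <- dft_amplitude(out$samples[trim], f, fs) /
      dft_amplitude(rec$samples[trim], f, fs)
    expect_gt(gain, 0.95)
    expect_lt(gain, 1.05)
  }
  rec60 <- ecg_recording(sin(2 * pi * 60 * tt), fs)
  out60 <- bandpass_ecg(rec60)
  gain60 <- dft_amplitude(out60$samples[trim], 60, fs) /
    dft_amplitude(rec60$samples[trim], 60, fs)
  expect_lt(gain60, 0.1)
})

test_that("band-pass validates parameters and is linear", {
  fs <- 180
  rec <- ecg_recording(rnorm(10 * fs), fs)
  expect_error(bandpass_ecg(rec, 0.5, 95), "Nyquist")
  expect_error(bandpass_ecg(ecg_recording(rnorm(100), fs)), "shorter")

  set.seed(11)
  x <- rnorm(5 * fs); y <- rnorm(5 * fs)
  fx <- bandpass_ecg(ecg_recording(x, fs))$samples
  fy <- bandpass_ecg(ecg_recording(y, fs))$samples
  fxy <- bandpass_ecg(ecg_recording(2 * x - 3 * y, fs))$samples
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
})

test_that("R-peak detection recovers clean pulse trains", {
  g <- synth_rr(rr_gen_spec(duration = 60, base_rr = 1000, seed = 1))
  se <- synth_ecg(g$rr, 180)
  pk <- detect_r_peaks(bandpass_ecg(se$ecg))
  expect_gte(length(pk$times), 59)
  expect_lte(length(pk$times), 62)
  expect_true(all(abs(diff(pk$times) - 1) < 0.01))
})

test_that("R-peak detection handles flat input and noise", {
  expect_warning(pk0 <- detect_r_peaks(ecg_recording(rep(0, 720), 180)),
                 "flat")
  expect_length(pk0$times, 0)

  # 80 bpm with additive noise at SNR 10 dB
  g <- synth_rr(rr_gen_spec(duration = 60, base_rr = 750, jitter_sd = 20,
                            seed = 2))
  se <- synth_ecg(g$rr, 180, noise_sd = 10^(-10 / 20))
  pk <- detect_r_peaks(bandpass_ecg(se$ecg))
  expect_gte(match_rate(se$truth$r_times, pk$times, 0.05), 0.95)
})

test_that("rr_from_peaks is the first-difference operator", {
  pk <- rpeak_series(c(0, 1, 2, 3))
  rr <- rr_from_peaks(pk)
  expect_equal(rr$intervals, c(1000, 1000, 1000))
  expect_equal(rr$times, c(1, 2, 3))
  expect_equal(rr_from_peaks(rpeak_series(c(0, 0.8, 1.7)))$intervals,
               c(800, 900))
  expect_error(rr_from_peaks(rpeak_series(1.5)), "2 peaks")

  set.seed(3)
  tt <- cumsum(runif(300, 0.5, 1.5))
  rr2 <- rr_from_peaks(rpeak_series(tt))
  expect_equal(rr2$intervals, (tt[-1] - tt[-300]) * 1000)
})

test_that("ectopic correction repairs the premature-beat short-long pattern", {
  x <- rep(800, 60); x[30] <- 400; x[31] <- 1200
  out <- correct_ectopic(rr_series(x))
  expect_true(all(abs(out$intervals - 800) < 50))
  expect_gte(sum(out$quality_flags != "ok"), 1)
  # times/interval identity preserved
  expect_equal(diff(out$times) * 1000, out$intervals[-1], tolerance = 1e-9)
})

test_that("ectopic correction splits missed beats and merges extra beats", {
  y <- rep(800, 60); y[30] <- 1600
  out <- correct_ectopic(rr_series(y))
  expect_equal(length(out$intervals), 61)
  expect_true(all(abs(out$intervals - 800) < 50))

  # extra detection: one 800 split into 350 + 450
  z <- c(rep(800, 29), 350, 450, rep(800, 29))
  out2 <- correct_ectopic(rr_series(z))
  expect_equal(length(out2$intervals), 59)
  expect_true(all(abs(out2$intervals - 800) < 50))
})

test_that("ectopic correction is idempotent and leaves clean series alone", {
  clean <- correct_ectopic(rr_series(rep(800, 60)))
  expect_equal(clean$intervals, rep(800, 60))
  expect_true(all(clean$quality_flags == "ok"))

  x <- rep(800, 80); x[c(20, 50)] <- 400; x[c(21, 51)] <- 1200
  once <- correct_ectopic(rr_series(x))
  twice <- correct_ectopic(once)
  expect_equal(twice$intervals, once$intervals, tolerance = 1e-12)

  g <- synth_rr(rr_gen_spec(duration = 120, base_rr = 800,
                            modulations = list(list(freq = 0.1, amp = 60,
                                                    phase = 0)),
                            jitter_sd = 10, ectopic_rate = 0.03, seed = 4))
  once2 <- correct_ectopic(g$rr)
  twice2 <- correct_ectopic(once2)
  expect_equal(twice2$intervals, once2$intervals, tolerance = 1e-12)
})

test_that("unsalvageable series are marked excluded", {
  set.seed(5)
  x <- runif(40, 300, 2000)   # chaos: most intervals deviate from local median
  out <- correct_ectopic(rr_series(x))
  expect_true(out$excluded)
})

test_that("quality screening applies the 10%-of-windows rule monotonically", {
  g <- synth_rr(rr_gen_spec(duration = 600, base_rr = 800, jitter_sd = 10,
                            seed = 6))
  scr <- screen_quality(g$rr)
  expect_equal(scr$verdict, "keep")
  expect_equal(scr$bad_frac, 0)

  corrupt <- function(rr, frac_windows) {
    flags <- rr$quality_flags
    starts <- seq(0, max(rr$times), by = 30)
    nbad <- ceiling(frac_windows * length(starts))
    for (s in starts[seq_len(nbad)]) {
      in_w <- rr$times > s & rr$times <= s + 30
      flags[in_w] <- "suspect"   # whole window corrected -> poor
    }
    rr_series(rr$intervals, rr$times, flags)
  }
  expect_equal(screen_quality(corrupt(g$rr, 0.05))$verdict, "keep")
  expect_equal(screen_quality(corrupt(g$rr, 0.20))$verdict, "exclude")

  # monotone: adding corruption never flips exclude -> keep
  prev_bad <- -1
  for (f in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    bf <- screen_quality(corrupt(g$rr, f))$bad_frac
    expect_gte(bf, prev_bad)
    prev_bad <- bf
  }
})
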