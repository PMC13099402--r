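---
title: "HRV amplitude: model, preprocessing chain and statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV amplitude: model, preprocessing chain and statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvamp)
```

## The metric

Heart rate variability (HRV) indices built on fast beat-to-beat differences
(RMSSD, high-frequency power) isolate parasympathetic (vagal) cardiac
control. They are blind to a different physiological regime: simultaneous
engagement of both autonomic branches, where slow sympathetic drive and
phasic vagal activity together widen the *band* within which RR intervals
oscillate without necessarily changing the mean or the fast differences.

`hrvamp` quantifies that band directly. Given an RR-interval series
$RR_1, \dots, RR_n$ (ms) at beat times $t_1 < \dots < t_n$:

1. find the local maxima and local minima of the series (a point is a
   maximum when it exceeds its left neighbor and is at least its right
   neighbor; a plateau bounded by strictly smaller neighbors counts once,
   at its first point — this tie-break makes the operator deterministic and
   reproducible by a brute-force oracle);
2. take a centered moving **median of 5 consecutive maxima values** to form
   the upper envelope, and of 5 consecutive minima for the lower envelope;
3. anchor each median at its extremum's time, interpolate linearly to every
   beat time (constant beyond the first/last extremum);
4. the **HRV amplitude** is the difference, floored at zero:
   $A(t) = \max\{U(t) - L(t), 0\}$.

The median over extrema makes the envelope robust to isolated artifacts —
one outlier in a 5-point window cannot move the median — while preserving
local trends. A Hilbert-transform envelope was deliberately rejected: on
highly entropic RR series its analytic-signal magnitude is dominated by the
fastest components and does not track the visually evident band.

Two readings of "a window of five data points" are possible: five
consecutive *extrema* or five consecutive *beats*. This package adopts the
extrema reading — medians of extrema values are what make the construction
an envelope; a 5-beat window would usually contain at most two extrema and
reduce to a smoother of the raw series. The amplitude is computed on RR
intervals in ms, not on instantaneous heart rate: envelope differences of
the interval series have a direct ms interpretation and are
translation-invariant under mean-rate shifts, which the package verifies as
a property (amplitude of $RR + c$ equals amplitude of $RR$ to $10^{-9}$
relative, and amplitude of $c \cdot RR$ equals $c$ times the amplitude).

Both a per-beat amplitude (`envelope()`) and a 1 s resampled grid version
(`hrv_amplitude_timeseries()`) are provided; segment averaging uses the
uniform grid, so chapter means are time-weighted rather than beat-weighted.

## Preprocessing chain

**ECG filtering.** `bandpass_ecg()` applies a 120-tap FIR band-pass
(0.5–30 Hz at 180 Hz sampling by default) forward and backward, i.e.
zero-phase, so R-peak timestamps are not systematically delayed — the
timestamps feed every downstream metric. The signal mean is removed before
filtering because a 120-tap FIR at this rate leaves appreciable residual DC
and slow edge transients.

**R-peak detection.** `detect_r_peaks()` is a Pan–Tompkins-style detector:
5–15 Hz QRS-band restriction, derivative, squaring, 150 ms moving-window
integration, adaptive signal/noise running levels with the threshold placed
a quarter of the way up from noise to signal level, a searchback pass that
rescues sub-threshold beats inside gaps longer than 1.66 times the running
RR average at half threshold, refinement of each detection to the local
maximum of the lightly smoothed trace, and a 250 ms refractory period.
On synthetic ECG with additive white noise at SNR 10 dB the detector
matches ≥ 95 % of ground-truth beats within ±50 ms (verified in the test
suite at 60 and 80 bpm).

**Ectopic correction.** `correct_ectopic()` implements a dRR-threshold
procedure in the spirit of the widely used Kubios artifact corrector. Each
interval is compared against an 11-beat running median; the deviation
threshold is the larger of a relative bound (20 % of the local median) and
4.5 quartile deviations of the successive differences, so high natural
variability inflates the threshold and is not "corrected" away. Flagged
intervals are classified:

* **missed beat** — interval ≈ 2× local median: evenly spaced beats are
  inserted;
* **extra beat** — two adjacent intervals summing to the local median: the
  spurious beat is deleted;
* **ectopic (premature) beat** — short interval followed by a compensatory
  pause: the beat is *moved* to the position implied by cubic interpolation
  of neighboring accepted intervals.

Corrections operate on beat times rather than interval values, so the
identity $RR_i = (t_i - t_{i-1}) \cdot 1000$ and the total record duration
are preserved exactly, and the procedure is idempotent (a second pass
changes nothing). If more than half the intervals are initially deviant
under the relative criterion alone, the series is marked unsalvageable and
excluded; the quartile-deviation term is ignored for this verdict because
heavy corruption inflates it and would mask itself.

**Quality screening.** `screen_quality()` tiles the record into 30 s
windows (matching the RMSSD analysis window); a window is poor when more
than 20 % of its intervals were corrected or fall outside 250–3000 ms, and
the whole recording is excluded when more than 10 % of windows are poor.
The 10 % whole-record rule is the study-level exclusion criterion; the 20 %
per-window criterion is this package's documented default, configurable.
Both per-segment and whole-recording verdicts are reported, since either
exclusion policy may be wanted.

**Respiration.** `preprocess_resp()` applies a zero-phase second-order
0.05–3 Hz Butterworth band-pass; `detect_breaths()` uses zero-crossing
bracketed extremum search with a minimum breath duration of 1.5 s (at most
40 breaths/min) and an adaptive amplitude floor at 30 % of the median
candidate amplitude. Breath amplitude is peak minus immediately preceding
trough — the simplest convention consistent with impedance pneumography.
Because amplitude units are device-specific and uncalibrated across
participants, study-level analyses treat respiratory amplitude as rank
data (Spearman) only.

## Statistical battery

* `minmax_normalize()` — affine rescale to [0, 1], applied to the
  correlation battery's variables.
* `normality_gate()` — Shapiro–Wilk on each group; Mann–Whitney U when
  either rejects at 0.05, otherwise the independent t-test.
  `mann_whitney()` reports U (first-sample convention), a tie-corrected
  normal-approximation z, and an exact enumeration p for small tie-free
  samples.
* `partial_spearman()` — Pearson correlation of covariate-residualized
  ranks; degrees of freedom penalized by the number of covariates $k$
  (t reference with $n-2-k$ df; Fisher-z CI with sd $1/\sqrt{n-3-k}$).
  Gender enters as a binary indicator; other categorical covariates would
  be one-hot encoded with a reference level.
* `segmented_fit()` — hinge model
  $y = \beta_0 + \beta_1 x + \beta_2 (x-\psi)_+ + \text{covariates}$, with
  $\psi$ profiled over a 50-point quantile grid (10th–90th percentile of
  $x$) and refined by golden-section search between the bracketing grid
  points. The breakpoint CI uses the linearization (delta-method) standard
  error $\mathrm{se}(\gamma)/|\beta_2|$ from the locally linearized model;
  this is fast and accurate when the hinge is well supported, the regime in
  which a breakpoint is reported at all. The segmented fit is fitted on the
  *original* rating scale (the breakpoint must be interpretable in rating
  units); min-max scaling applies to the correlation battery only.
* `davies_test()` — the hinge t-statistic evaluated at K = 10 candidate
  breakpoints spanning the 10th–90th percentile; p-value from the Davies
  upper bound $2\,P(T \ge M) + V f_T(M)$ with $M$ the largest absolute
  statistic and $V$ the total variation across the grid. The correction
  term uses the **t density** matching the per-point reference
  distribution: with the normal-density version the empirical type-I rate
  at $n = 50$ sits near 0.08, while the t-density version (the correct
  form for studentized linear-model statistics) simulates at ≈ 0.04 —
  slightly conservative, as the bound should be.
* `mediation_bootstrap()` — OLS paths on z-scored complete cases, indirect
  effect $a \cdot b$, percentile bootstrap CIs (bias-corrected available)
  over 5000 case resamples with a fixed seed; degenerate resamples (any
  constant variable) are redrawn and counted. `total = direct + indirect`
  holds exactly for the point estimates.
* `fdr_adjust()` — Benjamini–Hochberg step-up. Which p-values form a family
  is never guessed: the pipeline config declares FDR families explicitly.

## Synthetic generators: what they emulate, and what not

The generators exist so that every pipeline stage can be scored against
known ground truth without any data download.

* `synth_rr()` — interval-level generation: the next interval equals the
  base RR plus sinusoidal modulations evaluated *in continuous time at the
  running beat time* (so modulation frequencies have physical Hz units and
  can be placed inside or outside the respiratory sinus arrhythmia band)
  plus white jitter. Ectopic events replace an interval by an early 0.5×
  beat followed by a 1.5× compensatory pause — the exact short-long pattern
  the corrector's ectopic branch must repair.
* `synth_ecg()` — a stereotyped QRS template (Gaussian R spike of 12 ms
  width flanked by Q/S dips) at each beat time, plus optional white noise;
  true R times are the beat times to sample resolution.
* `synth_resp()` — phase-integrated sinusoid with time-varying rate and
  amplitude profiles, covering paced breathing down to 5.5 cycles/min.
* `synth_cohort()` — participants with age/gender/BMI covariates, uniform
  ratings on 0–10, and HRV amplitude flat below a breakpoint of 7.0 and
  rising at 0.0218 per rating unit above it, plus covariate effects and
  Gaussian noise. The residual sd default (0.02) was calibrated once so
  that the rating–amplitude partial Spearman at $n = 44$ averages ≈ 0.47,
  the strength of association this cohort shape is meant to embody; at
  that noise level the Davies test is significant in roughly 60 % of
  cohorts — breakpoint detection at this scale is genuinely borderline,
  and the tests treat it as a majority-power property, not a certainty.
* `synth_session()` — three concatenated phases: 8 min baseline (base RR
  800 ms, 50 ms modulation at 0.1 Hz), 3 min sympathetic surge (620 ms,
  modulation suppressed to 12 ms), 17 min vagal rebound (780 ms, modulation
  elevated to 110 ms). These values were chosen once as physiologically
  plausible magnitudes for a short-acting pharmacological challenge; they
  guarantee by construction that the post-acute window (minutes 4–20 after
  the baseline/surge boundary) carries higher HRV amplitude than the acute
  window (minutes 0–3).

What the generators do **not** emulate: realistic ECG morphology
(P/T waves, baseline wander, electrode artifacts), non-stationary or
fractal RR dynamics, respiratory–cardiac phase coupling (RSA is emulated
only as an interval modulation at a respiratory frequency), movement
artifacts, or between-participant heterogeneity in signal quality. Passing
the recovery tests therefore demonstrates algorithmic correctness under
controlled conditions, not field performance on ambulatory recordings.

## Numerical choices and degenerate inputs

* Timestamps are seconds from recording start; intervals ms; 0-based
  sample indexing at acquisition, 1-based indices in R vectors.
* A constant RR series has no extrema; the envelope collapses to the
  series itself and the amplitude is exactly 0 (no error). Fewer than 5
  maxima or minima: the median window shrinks symmetrically and the result
  carries a `low_confidence` flag.
* Sliding windows are centered; causal alignment is available via the
  `align` argument and differs only by a time shift. RMSSD points need at
  least 3 intervals spanning at least 10 s.
* Zero-variance variables in correlations produce an explicit `NA` with a
  message, never a crash; rank-deficient covariate matrices raise an error
  naming the collinear columns.
* All generators, the bootstrap and the pipelines are deterministic under
  fixed seeds; re-running a study config reproduces every table
  bit-for-bit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
60 s ECG traces at 180 Hz for detector recovery, 5–10 min RR series for
envelope and screening properties, hinge cohorts of $n = 200$ over 30–50
seeds for breakpoint recovery, 1000 linear-null replicates at $n = 50$ for
the Davies type-I rate, 5000 bootstrap resamples at $n = 500$ for
mediation, and 20 null cohorts of $n = 200$ for the null-structure check —
the larger null-cohort size is deliberate, so that sampling noise
(sd ≈ $1/\sqrt{n}$) cannot masquerade as structure under the |rho| < 0.2
criterion.

## Known limitations

* The breakpoint CI is linearization-based; for weakly identified hinges a
  profile-likelihood CI would be wider and more honest — the degenerate
  case is flagged via `supported = FALSE` instead.
* The ectopic corrector handles isolated and moderately clustered
  artifacts; runs of consecutive ectopics longer than the running-median
  half-window can bias the local median itself.
* Respiratory amplitude is unit-free across devices; only rank-based
  analyses of it are meaningful.
* The Mann–Whitney exact path enumerates only tie-free small samples;
  ties always route to the corrected normal approximation.
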