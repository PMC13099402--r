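Package: hrvamp
Title: Envelope-Based Heart Rate Variability Amplitude Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying dynamic sympathovagal engagement from the
    electrocardiogram via the HRV amplitude metric: the difference between
    moving-median envelopes of local maxima and minima of the RR-interval
    series. Includes a full cardiorespiratory preprocessing chain (FIR/IIR
    band-pass filtering, R-peak detection, ectopic-beat correction via a
    dRR-threshold procedure, quality screening, sliding-window RMSSD and
    heart rate, respiratory rate and amplitude extraction), the statistical
    battery used to relate the metric to subjective ratings (partial
    Spearman correlation with covariates, segmented regression with a
    Davies pseudo-score test, bootstrap mediation, Benjamini-Hochberg FDR),
    study-level analysis pipelines, and a synthetic cardiorespiratory data
    generator providing ground truth for every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
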