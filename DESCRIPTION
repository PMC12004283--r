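Package: hrvaffect
Title: Ultra-Short-Term Heart Rate Variability Analysis of Affective
    Stimulation Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of single-lead ECG recorded during
    block-design affective video stimulation: Butterworth high-pass and
    notch filtering, FFT resampling, Pan-Tompkins R-peak detection,
    automated ectopic-beat correction under a 20 percent rejection rule,
    twelve ultra-short-term heart rate variability measures per 55-second
    protocol window, rest-referenced normalization scaled by the
    subject-level median absolute deviation, and nonparametric
    group/condition comparisons (Wilcoxon signed-rank and rank-sum tests
    with Bonferroni correction and r effect sizes). A seeded synthetic
    cohort generator emulates the stimulation protocol, autonomic
    modulation of the heart period, ECG waveform synthesis with realistic
    noise, and ectopic-beat injection, so every pipeline stage is testable
    against ground truth without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
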