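Package: ecgqc
Title: Signal-Quality Scoring of Alternative ECG Electrodes Against a
    Reference Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how faithfully an alternative ECG
    electrode (for example a dry textile electrode) reproduces the signal
    of a simultaneously recorded reference Ag/AgCl channel. Provides
    zero-phase Butterworth preprocessing, an R-peak detector built on
    continuous-wavelet-transform scalograms and a trainable per-sample
    Q/R/S classifier with correlation-based beat verification, a classical
    Pan-Tompkins comparator, median-cardiac-period extraction with P/QRS/T
    segmentation, the quality indices Pearson R, SNR (dB) and PRD (%),
    R-peak amplitude-difference analysis, nonparametric group comparison
    (Shapiro-Wilk gate, exact Mann-Whitney), and a fully seeded synthetic
    paired-electrode ECG generator that makes every stage testable without
    access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nnet,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
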