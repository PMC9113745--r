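Package: sleepmicro
Title: NREM Sleep EEG Microarchitecture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of non-rapid-eye-movement (NREM)
    sleep EEG microarchitecture: slow and fast sleep spindles (complex Morlet
    wavelet detector with band-ratio quality control), slow oscillations
    (zero-crossing detector with absolute or adaptive amplitude thresholds),
    slow-oscillation/spindle phase coupling with surrogate-normalized Z-scores,
    intra-spindle instantaneous-frequency dynamics (chirp and phase/frequency
    modulation), Welch spectral power, spectral slope, magnitude-squared
    coherence and normalized phase-slope-index connectivity, covariate-adjusted
    case/control statistics with min-p permutation correction, and
    SVD-component (principal spectral component) reduction with out-of-sample
    projection and optimism-corrected prediction. Includes a synthetic
    multichannel EEG and cohort generator with ground-truth events so the full
    pipeline is testable without clinical recordings, plus EDF and
    stage-annotation I/O and a Hjorth-parameter artifact pipeline with
    spherical-spline interpolation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
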