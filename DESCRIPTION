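Package: rrfuse
Title: Respiratory Rate and Uncertainty Estimation from PPG and ECG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates respiratory rate (breaths per minute) with predictive
    confidence intervals from photoplethysmography (PPG) and electrocardiogram
    (ECG) waveforms. Implements the full pipeline: synthetic dual-signal cohort
    generation with known respiratory modulation, Kaiser-window FIR
    preprocessing with adaptive pulse segmentation and fiducial extraction,
    hybrid feature extraction (autocorrelation power-spectral features plus
    multi-phase wavelet features: Burg autoregressive coefficients,
    wavelet-packet Shannon entropies, multifractal wavelet-leader log-cumulants
    and MODWT wavelet variances), weighted feature fusion with feature
    selection by robust neighborhood component analysis, exact Gaussian
    process regression with explicit basis functions and 95% predictive
    intervals, and a repeated grouped-split evaluation harness with one-way
    ANOVA model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
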