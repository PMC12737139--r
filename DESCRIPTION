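Package: aldtf
Title: Adaptive Layer-Dependent Threshold Wavelet Denoising for
    Quasi-Periodic Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free wavelet denoising of quasi-periodic physiological
    signals such as electrocardiograms and fiber-optic cardiorespiratory
    recordings. Implements an adaptive layer-dependent tanh threshold function
    applied to discrete wavelet transform detail coefficients (biorthogonal
    6.8 wavelet), with the per-layer tuning factor selected by maximizing the
    non-zero periodic peak of the normalized autocorrelation of the
    reconstructed signal, so no clean reference is needed. Includes classical
    soft/hard threshold baselines, reference-based quality metrics (SNR,
    SINAD, RMSE, PRD), seeded generators for ECG-like and
    cardiorespiratory-like test signals with baseline-wander, electrode-motion,
    muscle-artifact and mixed noise, CSV/JSON input-output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
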