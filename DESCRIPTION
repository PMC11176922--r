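Package: breathecast
Title: Cyclic Decomposition and Recurrent Forecasting of Respiratory Surrogate Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for latency compensation in motion-managed radiotherapy:
    preprocessing of anterior-posterior surface-displacement breathing traces
    (uniform resampling, cropping, zero-phase Butterworth low-pass filtering),
    decomposition of the quasi-periodic signal into breathing phase, deflection
    and baseline through a modulated-cosine model, dynamic per-window
    normalization, and small stacked-LSTM predictors that forecast the signal
    500 ms ahead either directly or through the cyclic components. Includes a
    synthetic respiratory-waveform generator with per-cycle amplitude and
    period variation, amplitude and baseline drift, and an end-exhale dwell
    shape parameter, plus RMSE-based evaluation with circular phase errors and
    amplitude-group cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
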