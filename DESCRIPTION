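Package: actiplex
Title: Complexity Analysis of Actigraphy During Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear time-series analysis of body-movement (actigraphy)
    recordings during sleep. Implements the full analysis chain from raw
    tri-axial acceleration to cohort-level statistics: block-average
    resampling, high-pass filtering, RMS magnitude, sleep-onset anchoring and
    median binarization; a chi-square stationarity screen; iterative
    amplitude-adjusted Fourier transform (IAAFT) surrogates with Welch
    spectral verification; false-nearest-neighbors determinism detection with
    autocorrelation-time delay selection; approximate entropy, sample entropy
    and the time-resolved expanded sample entropy (expSampEn) at multiple
    time scales; detrended fluctuation analysis of long-range temporal
    correlation; and two-group comparison statistics (pointwise t-tests on
    smoothed irregularity tracks, high/low-irregularity representative
    values, Spearman cross-measure tables). A regime-switching synthetic
    actigraphy generator provides reproducible cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
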