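Package: emgswn
Title: Sliding-Window Normalization for Electrode-Shift-Robust EMG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time surface-EMG motion classification that is robust
    to electrode shift. Implements causal sliding-window z-score normalization
    (SWN) in batch and streaming forms, the surrounding causal preprocessing
    chain (band-pass Butterworth filtering in second-order sections, decimation,
    rectification, windowed frame assembly), a from-scratch CNN-LSTM sequence
    classifier with optional gradient-reversal domain adaptation and focal loss,
    the four training regimes used to benchmark shift robustness (single-position,
    transfer learning, adversarial domain adaptation, multi-position mixing),
    differential classification accuracy evaluation, nonparametric statistics
    (Wilcoxon rank-sum, Bonferroni, Scheirer-Ray-Hare), and a synthetic
    multi-channel EMG generator with a parametric electrode-shift model for
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
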