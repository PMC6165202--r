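Package: earbci
Title: Ear-EEG Analysis for an Endogenous Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for endogenous brain-computer interface (BCI)
    experiments recorded with combined scalp and behind-the-ear (ear-EEG)
    electrodes. Implements electrode montage and paradigm schedule definitions,
    a synthetic multichannel EEG generator with known ground-truth effects
    (occipital alpha leaking to ear channels, task-related alpha
    synchronization and beta/gamma desynchronization, 1/f background, blink
    artifacts), signal conditioning (zero-phase Butterworth filtering,
    downsampling, common average and opposite-ear referencing, epoching,
    baseline correction, peak-to-peak artifact rejection), spectral analysis
    (short-time Fourier transform, eyes-closed/eyes-open alpha
    signal-to-noise ratio, event-related desynchronization/synchronization
    maps), multi-band common spatial pattern feature extraction with
    shrinkage linear discriminant analysis classification under repeated
    stratified cross-validation, and region-of-interest group statistics
    (Friedman, Wilcoxon signed-rank, Bonferroni).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
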