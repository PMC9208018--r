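Package: ordinet
Title: Ordinal-Pattern Entropy and Network Coupling Analysis for
    Multichannel Neurophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Symbolic (ordinal-pattern) analysis of multichannel neural time
    series.  Implements local permutation entropy and the inverted joint
    permutation entropy, a network-level measure of nonlinear coupling with a
    built-in correction for volume conduction/field spread that excludes
    identical and mirrored ordinal-pattern pairs.  Includes FFT band-pass
    filtering in canonical frequency bands, relative band power,
    nonparametric group comparison by permutation testing with
    false-discovery-rate control, single-feature logistic classification
    with ROC analysis, one-way ANCOVA, and a synthetic two-group cohort
    generator with tunable oscillatory content, lagged coupling, and
    zero-lag leakage for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    pROC,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
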