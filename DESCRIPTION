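Package: lamcsd
Title: Laminar Current Source Density Analysis of Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of laminar local field potential (LFP)
    recordings acquired during auditory Go/NoGo reversal learning. Provides a
    synthetic generator for 32-channel columnar recordings and shuttle-box
    behavior, signal-detection (d-prime) performance phases, current source
    density (CSD) and AVREC estimation with spatial Hamming smoothing and
    artifact screening, windowed RMS features, Morse-wavelet time-frequency
    power, cluster-mass permutation statistics with extent and Cohen's d
    gating, repeated-measures ANOVA with generalized eta-squared, and
    mixed-logistic effect-size (marginal/conditional R-squared) series, plus a
    configuration-driven pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
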