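Package: erpfactor
Title: Simulation, Mass-Univariate Localization and Bayes-Factor Model
    Comparison for Factorial ERP Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing event-related potential (ERP) experiments with
    fully crossed within-subject factorial designs.  Provides a synthetic
    multichannel ERP study generator with known ground truth (trial schedules,
    1/f background noise, component topographies calibrated in microvolts), the
    standard EEG preprocessing chain (linear detrending, re-referencing,
    Hamming windowed-sinc FIR filtering, spherical-spline interpolation of bad
    channels, epoching and baseline correction), mass-univariate component
    localization via the t-max permutation procedure with family-wise error
    control, single-trial amplitude and peak extraction over electrode
    clusters, Jeffreys-Zellner-Siow Bayesian t-tests and default g-prior
    Bayes factors for factorial linear models with participants as a random
    nuisance factor, top-down term-omission analyses, and a pre-registered
    sequential Bayes-factor stopping rule orchestrated into an end-to-end,
    reproducible study workflow.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
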