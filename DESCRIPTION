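Package: melotrf
Title: Melodic Expectation Models and Temporal Response Function Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic models of melodic expectation (a Bayesian
    Gestalt-style pitch model and variable-order n-gram statistical
    learning models) with note-level surprise and uncertainty, plus
    time-resolved deconvolution regression (temporal response functions /
    regression evoked responses) of multichannel neural recordings:
    design-matrix time expansion, OLS and ridge estimation, cross-validated
    predictive correlation, model comparison with Bonferroni-Holm
    correction, and cluster-based permutation statistics with threshold-free
    cluster enhancement. Includes generators for synthetic melodies with
    known statistical structure and neural recordings with known
    ground-truth kernels, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
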