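Package: painseq
Title: Confidence-Weighted Statistical Learning of Thermal Pain Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of temporal statistical learning for
    binary (cool/hot) thermal stimulus sequences with Markovian structure.
    Implements six sequence-learning models (Bayesian ideal observers with
    leaky integration and Rescorla-Wagner delta rules, each tracking item
    frequency, alternation frequency, or transition probabilities), BIC-based
    behavioral model comparison with random-effects Bayesian model selection
    and Bayesian model averaging over the integration time constant, and
    mass-univariate single-trial regression of epoched EEG on model confidence
    and prediction error with FDR-corrected group statistics. A synthetic-data
    generator emulates the stimulus sequences, probability/confidence ratings,
    and biphasic vertex-potential epochs so the full pipeline runs without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
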