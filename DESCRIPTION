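Package: bcghf
Title: Heart-Failure Screening from Ballistocardiography and Respiratory
    Effort Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning-aided detection of heart failure from
    a single-channel piezoelectric force sensor. Separates the
    ballistocardiogram (BCG) and the respiratory effort component from the raw
    signal without locating individual heartbeats, removes artifacts by
    peak-to-mean-ratio screening, cuts 30-second epochs and scores their
    quality, extracts a 33-feature set spanning linear (amplitude, windowed
    power), non-linear (fuzzy entropy, largest Lyapunov exponent, correlation
    dimension, maximal information coefficient) and cardiopulmonary-coupling
    descriptors, and evaluates K-nearest-neighbour, support-vector-machine,
    random-forest and gradient-boosted classifiers under leave-one-out and
    leave-one-subject-out cross-validation. A seeded synthetic
    cardiorespiratory signal generator with ground truth makes the whole
    pipeline testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
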