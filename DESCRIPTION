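Package: neurobandit
Title: Volatile Kalman Filter Modeling and Prefrontal Coupling Statistics
    for Restless-Bandit Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for adaptive stay/switch
    decision-making in a three-armed restless bandit: simulation of the
    drifting reward environment and learning agents, a family of
    reinforcement-learning observers (Rescorla-Wagner, Kalman filter,
    volatile Kalman filter) with softmax choice rules over relative value
    and relative uncertainty, MAP and empirical-Bayes hierarchical model
    fitting with exceedance-probability model selection, generation of
    synthetic two-region local field potentials with ground-truth injected
    effects, Morlet time-frequency decomposition and Gabor-filter-bank
    analytic amplitude, phase-amplitude and amplitude-amplitude coupling
    with permutation nulls, and mixed-effects regression surfaces with 2D
    cluster-based permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    lme4,
    lmerTest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
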