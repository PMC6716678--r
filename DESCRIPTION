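Package: syncrl
Title: Learning to Synchronize Neural Task Modules by Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of a hierarchical cognitive-control
    architecture in which a reinforcement-learning controller gates a classic
    task-learning network through oscillatory synchronization (binding by
    random bursts). Coupled excitatory-inhibitory phase oscillators gate
    rate-code neurons; a theta-paced medial-frontal node emits correlated or
    anticorrelated noise bursts that (de)synchronize gamma-band task modules;
    a reward-value prediction circuit with a switch accumulator decides which
    module to synchronize. Includes reversal-learning task generators,
    Rescorla-Wagner and backpropagation learning rules with and without
    synchrony, stability and plasticity scores, learning-rate and oscillator
    parameter sweeps, and MEG/EEG-style analyses: zero-lag synchrony, debiased
    phase-amplitude coupling (dPAC), Morlet wavelet time-frequency power and
    error-minus-correct feedback contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
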