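Package: porekin
Title: Single-Molecule Kinetic Analysis for Nanopore Protein Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and statistical analysis of single-channel current
    recordings from nanopore protein sensors. Provides continuous-time Markov
    (Gillespie) simulation of capture/release gating rendered to realistic
    filtered, noisy current traces; threshold-based event idealization with
    blockade-amplitude mixture modelling; maximum-likelihood dwell-time
    inference with deadtime truncation, log-likelihood-ratio model selection
    and aggregated-Markov (rate-matrix) dwell densities including captured-
    substate interconversion; concentration-series estimation of association
    and dissociation rate constants and equilibrium dissociation constants;
    analyte quantification from calibrated kinetics; and Welch power spectral
    density estimation with white versus 1/f flicker noise classification.
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
    graphics,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    signal,
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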