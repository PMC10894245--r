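Package: tcdcm
Title: Thalamocortical Conductance Models Fitted to EEG Cross-Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-node, eight-population thalamocortical conductance
    neural mass model with explicit AMPA, NMDA and GABA-A receptor kinetics
    to EEG-derived cross-spectral densities by variational Laplace
    (free-energy) optimisation, in the style of dynamic causal modelling for
    steady-state spectral responses. Includes the spectral feature pipeline
    (epoching, Welch cross-spectra, band filtering, Hilbert envelopes), a
    synthetic-cohort generator with planted pharmacological effects and
    clinical-change scores, and group-level statistics (repeated-measures
    ANOVA, Benjamini-Hochberg FDR, Pearson correlations) with tidy report
    objects and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
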