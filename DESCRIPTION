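Package: fraccum
Title: Fractional-Cumulant Classifiers for Pairwise Effective Connectivity
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the direction of causal connections between
    brain regions from BOLD fMRI time series. Implements a generative forward
    simulator (bilinear neuronal dynamics with Balloon-Windkessel
    hemodynamics, Poisson-switching inputs, and optional scale-free
    background noise), fractional complex moments and cumulants of
    normalized signal distributions, a supervised sign-map voting classifier
    for pairwise direction calls, a partial-correlation first stage with
    permutation thresholding, reference direction methods (Patel's tau,
    pairwise likelihood-ratio robust skew, bivariate Granger causality,
    bivariate partial directed coherence), and robustness experiments over
    noise-variance and input-strength grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
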