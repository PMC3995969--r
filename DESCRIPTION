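Package: geomoran
Title: Bayesian Geostatistical Moran Curve Analysis of Vector Count Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decomposes monthly georeferenced count data from fixed transect
    surveys into fertility, density-dependent and density-independent losses
    using the Moran curve (the logarithmic Ricker stock-recruitment curve),
    fits a non-separable spatio-temporal Gaussian model to the residual
    structure by adaptive MCMC, selects the demographic parameterisation by
    DIC over a candidate grid, maps seasonal net population change by simple
    kriging, and validates predictions out of sample. Includes a synthetic
    data generator emulating tsetse fly-round surveys so the whole pipeline
    is testable end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
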