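Package: causalobs
Title: Bayesian Causal-Inference Observer Models for Audiovisual Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and simulates Bayesian observer models of audiovisual spatial
    localization and causal inference. Provides parametric and semiparametric
    (pivot-based) prior and eccentricity-dependent sensory-noise shapes, an
    auditory range recalibration gain, three causal-inference strategies (model
    selection, model averaging, probability matching), a trapezoidal-quadrature
    likelihood engine for unisensory and bisensory localization and causal
    judgment tasks, a sampling-path response simulator, maximum-likelihood
    fitting with multi-start optimizers, AIC/BIC model comparison with
    participant-level bootstrap, and model- and parameter-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
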