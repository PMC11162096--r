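Package: bqdesign
Title: Bayesian Quasi-Likelihood Dose-Ranging Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design and simulation engine for Bayesian quasi-likelihood
    dose-ranging (BQD) phase II trials. Models binary toxicity with a
    beta-binomial and binary, ordinal or continuous efficacy with a
    quasi-Bernoulli likelihood, couples doses through weighted isotonic
    regression on posterior draws, screens doses for safety and futility,
    establishes proof-of-concept, selects the minimum effective dose and the
    maximum utility dose under a benefit-risk utility, and adaptively
    randomizes patients across stages. Includes a latent bivariate-normal
    outcome generator with a built-in scenario library, a Monte-Carlo
    operating-characteristics simulator, and calibration of the
    proof-of-concept cutoff to a target familywise type I error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
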