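Package: flyvir
Title: Fitness Costs of Naturally Transmitted Drosophila Viruses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for natural virus-exposure
    experiments in Drosophila. Provides pooled-Bernoulli maximum-likelihood
    prevalence estimation with 2-log-likelihood support intervals,
    transmission-rate estimates, an exact Fisher-Freeman-Halton test for
    r x 2 donor-group tables, purpose-built MCMC machinery (blocked Gibbs
    sampling for Gaussian mixed models and Metropolis-within-Gibbs for
    hurdle-Poisson mixed models), Bayesian hierarchical models of lifespan
    and of lifetime or early-life offspring production, posterior-predictive
    zero checks, simulation-based power analysis, and a synthetic experiment
    generator so every stage can be exercised and validated without the
    original raw data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
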