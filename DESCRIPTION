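Package: usdpower
Title: Design and Simulation-Based Analysis of Unidirectional Switch
    Designs with Binary Outcomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and analysing cross-sectional
    cluster-randomized trials that use unidirectional switch designs
    (parallel-group, delayed-start, stepped-wedge and full-pattern switch
    designs) with binary outcomes.  Enumerates switch patterns, computes
    uniform and variance-optimal cluster allocations with integer rounding,
    and checks identifiability of treatment-by-period interactions.
    Simulates individual-level and cluster-period aggregated data from a
    probit generalized linear mixed model with exchangeable or AR1 latent
    cluster effects, fits the random-intercept probit GLMM by adaptive
    Gauss-Hermite quadrature and the marginal probit model by generalized
    estimating equations with the cluster-robust sandwich covariance, and
    provides joint chi-squared, robust Wald and generalized score tests for
    the treatment-by-period interaction.  A Monte-Carlo study driver
    summarizes type I error, power, bias and confidence-interval coverage
    with Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
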