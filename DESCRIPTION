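Package: mortsen
Title: Parametric Mortality Senescence and Reproductive-Effort Models for
    Laboratory Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood fitting of parametric mortality models
    (Gompertz, Gompertz-Makeham, logistic, logistic-Makeham, Weibull, and
    a constant-hazard "no senescence" model) to individual adult lifespans
    from factorial diet-by-mating experiments, with treatment-structured
    baseline mortality and rate-of-ageing parameters, profile-likelihood
    confidence intervals, AIC model batteries with Akaike weights,
    likelihood-ratio tests for nested structures, bootstrap lifespan
    summaries, and an in-package random-intercept Gaussian mixed model for
    longitudinal male calling effort.  Includes a synthetic-cohort
    generator emulating a 2 sex x 2 diet x 2 mating cricket senescence
    study design so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    flexsurv,
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
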