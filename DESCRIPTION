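Package: svyord
Title: Survey-Weighted Ordinal Regression under Outcome-Dependent Sampling
Version: 0.1.0
Authors@R: person("svyord", "maintainers", email = "svyord@example.org",
    role = c("aut", "cre"))
Description: Maximum (pseudo-)likelihood estimation for four ordinal
    regression families (stereotype, adjacent-category logit,
    continuation-ratio logit, cumulative logit) with optional inverse
    sampling-fraction weights for outcome-dependent samples.  Provides
    design-based standard errors via influence-function linearization,
    delta-method inference for stereotype log-odds products, analytic
    results for the sampled-data model under outcome-dependent sampling,
    and a Monte Carlo engine that generates cohorts from an ordinal probit
    model, calibrates per-family true parameters, and summarises bias and
    efficiency (relative bias, relative error of standard errors, relative
    root mean squared error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
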