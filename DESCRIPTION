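Package: agedose
Title: Age-Varying Exposure-Response Models and Paediatric Dosing Rules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how exposure-response (E-R) model
    parameters vary with age in children and for deriving age-grouped
    dosing rules that target a specified response.  Implements linear and
    sigmoid Emax E-R models with age-varying parameters, a categorical-age
    regression benchmark, model-based recursive partitioning over age
    (with PALM-style global effects and bootstrap aggregation), Bayesian
    penalised B-splines with first-order random-walk priors, an optimal
    age-boundary search minimising a weighted dosing objective, and a
    simulation framework with Simpson-integrated accuracy and precision
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
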