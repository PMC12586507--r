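Package: tumordyn
Title: Tumor Growth Dynamics and Treatment Response Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nested logistic-growth ordinary differential equation models of
    tumor volume under dosed combination therapy, with Bayesian hierarchical
    parameter estimation by affine-invariant ensemble MCMC, prior predictive
    coverage checks, BIC model selection, time-resolved Sobol total-effect
    sensitivity analysis via Saltelli sampling, and three individualized
    prediction schemes (mouse-specific, leave-one-out, and group-informed via
    a treatment-resistivity correction). Includes a synthetic-cohort generator
    emulating longitudinal preclinical tumor-volume studies for end-to-end
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
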