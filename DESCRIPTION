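Package: popkdt
Title: Population Pharmacokinetics, Screening Limits and Detection Times
    for Flunixin in Horses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint plasma-urine population pharmacokinetic modelling of
    flunixin disposition in horses and its regulatory consequences.
    Implements the closed-form three-compartment intravenous bolus model
    with a proportional urine channel, log-normal between-subject
    variability and a combined residual-error model; a synthetic
    multi-country cohort generator emulating published study designs; an
    EM-type nonlinear mixed-effects estimator with bootstrap precision,
    covariate screening and model diagnostics; derivation of effective,
    irrelevant plasma and irrelevant urine concentrations by the Toutain
    approach; detection-time computation under screening-limit scenarios
    including Monte Carlo simulation of virtual populations; and
    MAP-Bayesian individualized withdrawal-time prediction from sparse or
    rich sampling.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
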