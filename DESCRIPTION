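Package: ionrbe
Title: Dose-Response, Isoeffect and RBE Inference for Ion-Beam Toxicity
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fractionated ion-beam normal-tissue
    toxicity experiments with a binary late endpoint.  Converts
    animal-level censored time-to-event records into actuarial response
    probabilities and effective sample sizes, fits maximum-likelihood
    dose-response curves to obtain the dose at 50% complication
    probability (TD50) with delta-method standard errors and Fieller 90%
    confidence limits, performs joint linear-quadratic isoeffect analysis
    across fraction numbers (alpha/beta ratio and biologically effective
    dose BED50), derives the relative biological effectiveness (RBE) and
    its low-dose limit RBE_max as ratios with propagated uncertainties,
    and benchmarks externally supplied model RBE tables against the
    experimental values (region-averaged deviations, polynomial LET
    trends, slope ratios).  A synthetic-cohort generator reproduces the
    statistical design of a multi-LET spread-out-Bragg-peak rat spinal
    cord study so that every stage of the pipeline can be exercised and
    validated without access to unpublished animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
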