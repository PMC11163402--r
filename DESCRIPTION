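Package: fcdecomp
Title: Variance Decomposition of Whole-Brain Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes variance in whole-brain functional connectivity
    similarity matrices into common, session, group (diagnosis, treatment
    response, sex), interaction, and individual components. Includes
    finite-impulse-response task regression and time-series preparation,
    Fisher-z connectivity estimation, per-region localization of effects,
    within-subject permutation paired t-tests with false-discovery-rate
    correction, summary-statistics two-way ANOVA, split-half reliability
    curves, and a synthetic-cohort generator with an analytic oracle for
    expected similarities so every stage can be validated without access
    to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    car
Config/testthat/edition: 3
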