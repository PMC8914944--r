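Package: nccdid
Title: Negative-Control-Corrected Difference-in-Differences for Fully
    Treated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the average treatment effect in the treated when an
    entire eligible cohort receives treatment and positivity fails, using
    negative control outcomes combined with difference-in-differences
    analysis. Provides naive treatment effects from time-period and
    genotype comparisons, negative control effects built by treatment-label
    switching, and negative-control-corrected effects, with step-change and
    slope-change linear models and year-specific rate-ratio count models
    fitted by estimating equations with an independence working
    correlation, covariate adjustment by conditioning or standardization,
    cluster (person-level) bootstrap confidence intervals and p-values, and
    a seeded synthetic registry generator with closed-form ground truth for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
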