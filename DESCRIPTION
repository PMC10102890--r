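Package: survode
Title: Prognosis Parameters for Cancer Survivors via Hazard-Driven
    Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of time-varying prognosis parameters
    for cancer survivors: conditional Delta-year survival, restricted mean
    residual lifetime (and time lost), cause-specific risks and their
    contrasts, and comparisons against the general population via Ederer I
    expected survival from demographic rate tables.  All parameters are
    expressed as solutions of ordinary differential equations driven by
    cumulative hazards; a generic plug-in solver driven by Nelson-Aalen
    estimates produces point estimates, and companion covariance and
    cross-covariance recursions with a delta-method transform step produce
    pointwise variances and confidence intervals for any smooth functional
    of the solution at two time points.  Includes seeded synthetic-data
    generators with closed-form truths, delimited-text readers and writers,
    a time-until-prognosis-level report, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
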