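Package: cureboot
Title: Cure Rate Estimation Under Insufficient Follow-Up with Bootstrap
    Tail Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of the cure rate (the asymptotic
    plateau of a survival function) from right-censored time-to-event
    data when follow-up may be insufficient. Implements the Kaplan-Meier
    plateau estimator, an extreme-value tail correction with a
    bootstrap-selected tuning parameter aggregated by the mean (EK) or
    by the median (EC), a mixture-cure Monte-Carlo simulation harness
    reporting bias, standard deviation and mean squared error, and
    diagnostics for the bootstrap distribution (skewness, draw export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
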