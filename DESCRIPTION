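Package: twostagescreen
Title: Construction and Predictive Validation of Two-Stage Language Screening Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating two-stage developmental screening
    instruments in which a parent-reported first stage is followed by a direct
    pediatric assessment restricted to first-stage failures. Provides a
    latent-ability cohort simulator calibrated to published late-talker
    screening samples, logistic risk modelling with likelihood-ratio backward
    elimination, word-list item reduction, composition of the total two-stage
    screening score, constrained cutoff estimation (fixed sensitivity or fixed
    positive predictive value), risk-tier stratification with stratum-specific
    diagnostic likelihood ratios, exact and log-method confidence intervals for
    accuracy statistics, DeLong and stratified-bootstrap paired ROC comparisons,
    McNemar paired accuracy tests, and Welch heteroscedastic group validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
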