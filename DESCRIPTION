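Package: hormrel
Title: Test-Retest Reliability and Design Planning for Repeated Hormone
    Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing whether single measurements of a peripheral
    hormone (e.g. plasmatic or salivary oxytocin) are reliable trait markers.
    Implements the two-way variance-components intraclass correlation
    (single measures, absolute agreement) with F-test and confidence
    interval, the within-subject coefficient of variation, Spearman-Brown
    projection of the number of repeated measurements needed for a target
    reliability, attenuation-corrected power planning for correlation
    studies, repeated-measures ANOVA with Greenhouse-Geisser correction and
    Tukey-adjusted paired post-hocs, bootstrap, multilevel and Bayes-factor
    correlations, and a seeded log-normal generator of pulsatile
    hormone-concentration datasets for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), car, withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
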