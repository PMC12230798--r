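Package: lupineIPM
Title: Seed-Bank Integral Projection Models for Soil-Microbiota Effects on
    Lupinus polyphyllus Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses a size-structured integral projection model
    (IPM) with a discrete seed-bank class for the perennial herb Lupinus
    polyphyllus grown under two soil-inoculum treatments (intact vs.
    autoclaved) and two origins (invasive Finnish vs. native North American
    populations). Provides a synthetic-data generator emulating the
    greenhouse design, vital-rate regression (logistic survival and
    flowering, Gaussian growth and flowering-shoot number, recruit-size
    moments), field fecundity estimation, midpoint-rule kernel
    discretization with eviction diagnostics, asymptotic population growth
    rates (dominant eigenvalue by power iteration), percentile bootstrap
    confidence intervals, and one-at-a-time proportional sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
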