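Package: robcomb
Title: Robust Combination of Dependent P-Values
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Global tests for combining p-values whose dependence structure
    is unknown or arbitrary. Implements the Cauchy combination test (CCT),
    the minimum-p (MinP) test with Sidak and Bonferroni calibration, and the
    robust two-stage tests MinP-CCT-MinP (MCM) and CCT-MinP-CCT (CMC), which
    combine the CCT and MinP p-values of the same input with a second MinP or
    CCT stage. Also provides Fisher's chi-square and Stouffer's z methods for
    independent p-values, three structured correlation models (AR(1),
    polynomial decay, and a rank-deficient singular model) with Monte-Carlo
    machinery for estimating type-I error and power of the combined tests,
    and a meta-analysis workflow that converts per-study odds ratios with 95%
    confidence intervals into directional p-values and combines them in two
    stages. A command-line interface covers combining, simulation, and
    meta-analysis runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
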