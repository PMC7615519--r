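Package: alphastream
Title: Online Error Rate Control for Streams of Hypothesis Tests
Version: 0.1.0
Authors@R:
    person("Maintainer", "alphastream", email = "maintainer@alphastream.dev",
           role = c("aut", "cre"))
Description: Test levels and rejection decisions for p-values that arrive one at
    a time, under online false discovery rate control (LORD, LORD++, SAFFRON,
    ADDIS, monotone alpha-investing) or online familywise error rate control
    (alpha-spending, online Sidak). Provides generalized alpha-investing wealth
    accounting, spending sequences with finite-horizon (bounded) variants,
    offline comparators (Benjamini-Hochberg, uncorrected testing), error-rate
    and power estimators, a Gaussian simulation testbed, a packaged platform
    trial example, and a command-line interface for streaming runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
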