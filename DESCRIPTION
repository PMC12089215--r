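Package: nomnet
Title: Evaluating Jingle and Jangle Fallacies from Nomological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for deciding whether two psychological
    measures assess the same construct (a jangle fallacy) or different
    constructs under one name (a jingle fallacy). Provides the modified
    Fisher-z test for the difference between two dependent correlations
    sharing one variable, Monte Carlo power analysis for that test, the
    double-entry intraclass correlation (ICC-DE) of two nomological-network
    correlation profiles with bootstrap percentile confidence intervals,
    context-specific redundancy thresholds of the form 1 - d/t derived from
    counted correlation differences, disattenuation utilities with a
    simulation comparing ICC-DEs from raw versus disattenuated profiles,
    and a synthetic-data generator for participant-level score tables with
    a known population correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
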