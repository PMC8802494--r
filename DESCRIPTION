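Package: crossurv
Title: Two-Sample Survival Tests for Crossing Hazards and Kaplan-Meier
    Curve Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A battery of eleven two-sample tests for differences in
    survival when hazards are non-proportional or crossing: the log-rank
    and Peto-Peto tests, Fleming-Harrington weighted log-rank tests, the
    multiple-direction log-rank combination test, the MaxCombo test,
    three restricted mean survival time (RMST) tests, the KONP sample
    space partition permutation tests, an integrated L1-distance (area
    between curves) permutation test, and a two-stage log-rank /
    crossing-hazards procedure.  Also provides reconstruction of pseudo
    individual patient data from digitized Kaplan-Meier curves with
    number-at-risk tables, and a seeded simulation harness for type-I
    error and power studies under proportional, early/late-difference
    and crossing-hazards scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
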