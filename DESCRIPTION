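Package: domarith
Title: Degree-of-Merger Complexity Analysis for Hierarchical Arithmetic
    Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models mental arithmetic on linear and quadratic digit sequences
    as rooted calculation trees, in both hierarchical (recursive) and flat
    (verbalized) representations, and quantifies their structural complexity
    with the Degree of Merger and seven competing factors. Provides a
    stimulus generator with the task's digit-exclusion rules and
    pseudorandomized session schedules, a synthetic-data module for
    region-level percent-signal-change datasets and three-region BOLD-like
    time series, no-intercept parametric factor-model fitting and ranking
    (least squares, deviation t-tests, random-intercept mixed models,
    likelihood ratios), and a desk-scale effective-connectivity study: an
    18-model bilinear model space, maximum-likelihood inversion through a
    canonical-HRF forward model, random-effects Bayesian model selection,
    and parameter-recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
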