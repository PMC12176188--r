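Package: taufast
Title: Fast Kendall Rank Correlation with Exact and Approximate Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes Kendall's rank correlation coefficient (tau-b) in
    O(n log n) time with Knight's sort-and-count-inversions algorithm,
    with full tie corrections, and provides inference around it: the exact
    small-sample test based on the recursive null distribution of the
    concordant-pair statistic, the tie-corrected normal approximation with
    optional continuity correction, normal-approximation confidence
    intervals at arbitrary levels, a pairwise correlation matrix with
    pairwise-complete handling of missing values, a squared-tau pseudo
    R-squared for count-data regressions, a definitional O(n^2) reference
    implementation for verification, a synthetic bivariate-normal sample
    generator with controllable ties, and a command-line interface for
    delimited text files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
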