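Package: invmem
Title: Memory Length of Rare Events in Physiological Interval Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inverse-statistics analysis of physiological interval time series
    (heartbeat R-R intervals, inter-breath intervals). Computes exit-time
    (first-passage) distributions for accelerating and decelerating rare events
    at a jump level rho given in units of the series standard deviation, builds
    increment-shuffled surrogate ensembles that preserve one-step statistics
    while destroying longer-range temporal order, and estimates the memory
    length tau_m as the point where the original and shuffled exit-time
    distributions merge. Includes synthetic generators with known memory
    structure (memoryless random walks, autoregressive increments of known
    order, clustered rare-event regimes), cohort-level profiles of tau_m across
    rho levels, and group comparison by two-way ANOVA with Bonferroni post-hoc
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
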