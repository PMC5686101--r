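Package: cmrsim
Title: Critical Mutation Rate Estimation on Two-Peak Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time evolutionary simulation of diploid populations on
    per-gene two-peak Hamming-distance fitness landscapes, with binomial
    per-base mutation, meiosis-style crossover, and triple-tournament
    replacement in discrete generations. Estimates the critical mutation
    rate (CMR) -- the per-base mutation rate at which 95% of runs lose the
    fitter, narrower peak within a generation cap, marking the transition
    from survival-of-the-fittest to survival-of-the-flattest -- by a
    coarse-to-fine mutation-rate sweep over batches of runs, and fits the
    resulting CMR curves against population size and gene number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
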