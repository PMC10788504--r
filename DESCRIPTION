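Package: avalanchr
Title: Neuronal Avalanche Transition Matrices for Task Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract neuronal avalanches and avalanche transition
    matrices (ATMs) from epoched, source-level brain recordings, estimate the
    branching ratio of the underlying cascade dynamics, test condition-dependent
    changes in avalanche propagation with multi-level permutation statistics
    (edge, group, node, outcome contrast, and performance correlation with
    functional-area nulls), and benchmark ATM features against a common spatial
    patterns (CSP) baseline for motor-imagery trial decoding. Includes a
    seeded synthetic-cohort generator that plants condition-dependent
    propagation edges with known ground truth, for validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
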