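Package: coexland
Title: Cross-Dataset Gene Co-Expression Landscapes and Module Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds robust gene co-expression networks from multi-study
    expression cohorts using leave-one-out minimum Pearson correlations,
    extracts degree-pruned (k-core) gene modules, and assigns landscape
    coordinates (spring-embedded x/y layout and a z-value equal to the
    highest correlation cutoff at which a gene remains in a network).
    Provides module-level statistics: mean pairwise co-expression with
    random-gene-set nulls, the network average clustering coefficient
    (NACC) for within- and between-module interconnectivity with
    subsampling significance tests, rank-based single-sample module
    activity scores, cross-dataset module conservation cores, and
    resampling tests for module-level effects in arrayed siRNA knockdown
    screens.  Includes a Gaussian factor-model simulator that generates
    multi-dataset cohorts with planted correlation modules, dataset-specific
    batch artifacts, covariate-dependent inter-module coupling, and
    knockdown screens with planted effects, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
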