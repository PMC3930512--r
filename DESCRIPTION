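Package: hybridqtl
Title: Expression QTL Mapping and Epistatic Network Analysis in Hybrid F2 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for expression quantitative trait locus
    (eQTL) analysis in an F2 intercross between two inbred lines, motivated by
    studies of hybrid male sterility in house mice. Implements hidden-Markov
    genotype probabilities on a marker/pseudomarker grid, single-QTL interval
    mapping by the EM algorithm and Haley-Knott regression, permutation-based
    significance thresholds with a separate X-chromosome stratum, Storey
    q-values, misexpression classification against parental controls,
    sliding-window detection of trans-eQTL hotspots with a
    chromosome-reassignment permutation null, hotspot co-localization tests
    against sterility QTL intervals, and covariate-conditional mapping of
    epistatic (interaction) eQTL with network summaries. A synthetic-cross
    generator with known ground truth (cis effects, master regulators of
    configurable dominance, pure epistasis, sterility phenotypes) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
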