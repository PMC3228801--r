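Package: comphot
Title: Comparative Retroviral Integration Hotspot Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic segments where two retroviral vectors (for
    example HIV- and MLV-derived gene-transfer vectors) show different
    integration-site densities. Integration sites are analysed per
    chromosome arm and strand on a coordinate system from which
    restriction-digest "blind regions" have been collapsed; each vector's
    integration density is estimated by Gaussian kernel density estimation
    with the bandwidth chosen by unbiased (least-squares, leave-one-out)
    cross-validation; pointwise variability bands built on the square-root
    scale are compared, and maximal segments where the two bands are
    disjoint become candidate comparative hotspots. Candidates are
    confirmed by odds-ratio Fisher exact tests under Bonferroni-Holm
    correction and can be annotated against gene, expression and
    chromatin-mark tracks. A seeded synthetic-data generator produces
    fully self-contained test scenarios with planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
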