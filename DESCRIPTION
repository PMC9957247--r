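Package: cnvst
Title: Copy Number Variation Regions and VST Population Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-differentiation analysis of copy number
    variation from read-depth CNV calls. Reads CNVnator-style per-sample call
    tables, applies high-confidence filters (e-value, normalized read depth,
    length), merges calls across samples into copy number variation regions
    (CNVRs) by single-base-pair intersection, estimates per-sample copy
    numbers, computes the VST differentiation statistic between two
    populations, selects top-percentile regions, and annotates them against
    gene and QTL intervals with hypergeometric term enrichment. Includes a
    deterministic two-population CNV call simulator with known ground truth
    for end-to-end validation, plus PCA and UPGMA clustering of samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
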