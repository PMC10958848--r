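Package: replicall
Title: Replicate-Based Consensus Calling and Benchmarking of Somatic SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving somatic single-nucleotide variant (SNV)
    calling with biological replicates. Reads per-replicate somatic VCF call
    sets, restricts them to evaluable BED regions, computes m-of-n consensus
    variant sets under within-center, cross-center and all-centers grouping
    schemes, and benchmarks any call set against a high-confidence truth set
    with precision, recall and F1. Includes a seeded multi-center study
    simulator (truth set with a VAF spectrum, coverage-dependent caller
    sensitivity, and center-shared, caller-shared and private false-positive
    pools) and a consensus-label training harness that compares classifiers
    trained on consensus-derived labels against truth-trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
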