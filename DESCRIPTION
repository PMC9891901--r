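Package: riboStall
Title: Translatome Dynamics Analysis of Early Elongation Stalling from
    Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing perturbations of translation
    elongation from ribosome profiling, disome profiling, and CLIP-type
    sequencing data in transcript coordinates. Implements P-site offset
    calibration with 3-nt periodicity screening, per-transcript polarity
    scores and hierarchical clustering of perturbation conditions,
    start/stop-anchored metagene profiles, a negative-binomial Wald test
    for classifying elongation-repressed versus initiation-repressed
    genes, poly-purine motif-anchored footprint and disome density
    enrichment, k-mer enrichment in CLIP read libraries, and sliding
    window sequence-feature profiles (tAI, cAI, charge, hydrophobicity).
    A synthetic-data generator with known ground truth emulates control,
    initiation-block, and elongation-stall regimes for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
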