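Package: polycre
Title: Co-Occupancy and Chromatin-State Analysis of Polycomb Response
    Elements at Developmental Enhancers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate Polycomb response elements (PREs) from
    ChIP-seq peak sets of the two PhoRC subunits (Pho and dSfmbt) by
    replicate reconciliation and co-occupancy calling, annotates co-bound
    regions against promoters and two tiers of developmental enhancers
    with exclusive TSS-distance rules, tests overlap enrichment against
    matched background regions with Fisher's exact test, builds
    H3K27me3/H3K27ac meta-profiles with bootstrap confidence bands,
    classifies PhoRC-bound promoters into focused versus broad
    (Polycomb-repressed) H3K27me3 states, detects nucleosome-depleted
    regions, discovers the Pho recruitment motif de novo with a ZOOPS
    expectation-maximization model, and associates bound elements with
    nearest-gene expression (RPKM). A synthetic-genome module generates
    peak sets, signal tracks, sequences and expression counts with planted
    ground truth so every step of the pipeline can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
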