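Package: cageqtl
Title: Promoter Usage and Enhancer Activity QTL Mapping from CAGE Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end mapping of genetic variants to promoter usage (puQTLs)
    and enhancer activity (eaQTLs) from CAGE 5' tag counts. Provides TPM/RLE
    normalization of CAGE peak expression, permutation-based cis-QTL mapping
    within TAD windows with Storey q-value control, classification of
    puQTL-associated genes into five promoter-usage groups, density-based CAGE
    tag clustering and bidirectional eRNA detection for enhancer activity
    quantification, and integration statistics (pi1 replication, regulatory
    trait concordance, matched-permutation GWAS enrichment, causal inference
    testing on variant-enhancer-promoter triplets). A synthetic-data module
    simulates LD-structured genotypes and negative-binomial CAGE tag counts
    with planted regulatory effects so the whole pipeline is testable against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
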