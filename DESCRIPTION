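Package: strainMotif
Title: Strain-Specific Motif Disruption and Expression Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate regulatory variants that distinguish two
    inbred mouse strains by combining allele-specific transcription-factor
    binding-site scoring with a strain-by-treatment expression interaction
    statistic. Reconstructs paired reference/alternative allele windows
    around strain-difference SNPs, scores both alleles on both strands with
    position weight matrices (HOCOMOCO text format with score-to-p-value
    threshold tables), computes the delta motif-specificity statistic and
    the Z strain-specific treatment-response statistic, annotates hits with
    the nearest gene, integrates promoter methylation with expression via
    rank correlations, summarises a catalog of dysregulated target RNAs,
    and ships a seeded synthetic-data generator with planted
    SNP-motif-expression structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
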