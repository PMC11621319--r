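Package: poolmux
Title: Genotype-Based Demultiplexing of Pooled Single-Cell RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns genotype-deconvoluted single-cell clusters back to the
    patients of a multiplexed pool by matching cluster SNP profiles against
    per-patient bulk RNA-seq (or exome) variant calls. Cluster and patient
    genotype profiles are harmonized across VCF files, compared with a
    normalized Hamming distance over co-typed loci, and matched one-to-one
    with the Kuhn-Munkres (Hungarian) algorithm; per-cell labels are then
    propagated from a Souporcell-style barcode table. Also provides a-priori
    cohort SNP diversity evaluation for pool design, genomic-region
    stratification of recovered SNPs, precision/recall benchmarking with a
    bulk-SNP downsampling harness, doublet-overlap comparison, and a
    synthetic-cohort simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
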