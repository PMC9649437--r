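Package: sptdt
Title: Stratified Polygenic Transmission Disequilibrium and Regional
    Genomic Association
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for locating regions of the genome carrying an excess of
    a trait's common polygenic influences using parent-child trios.
    Implements the polygenic transmission disequilibrium test (pTDT) and
    its stratified extension (S-pTDT), genome partitioning into SNP-count
    blocks and fixed-length windows with gap-capped effective lengths,
    linear polygenic scoring from dosages or VCF genotypes, residual
    z-scores correcting regional transmission for SNP count and partition
    length, structural and gene-composition annotation of partitions,
    regional polygenic-score/gene-expression association with a
    within-cohort permutation null, a copy-number-variant regional
    differential-expression contrast, Hi-C within-region contact scoring
    with a distance-matched distal enrichment test, and a seeded
    liability-threshold simulator that generates every input class so the
    full pipeline runs without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
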