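Package: triosv
Title: Trio Long-Read Structural Variant Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural variants (SVs) and single
    nucleotide variants (SNVs) called from long-read sequencing of
    parent-offspring trios. Implements call-set matching between
    technologies (breakpoint distance and size-ratio rules, reciprocal
    overlap against external SV sets), Mendelian inheritance error
    quantification, de novo SV/SNV candidate filtering with
    evidence-based classification, gene-level recessive (homozygous and
    compound heterozygous SV-SNV) candidate detection, cross-technology
    coverage accessibility partitioning with GC-content comparison, and
    coverage-titration precision/recall curves. A seeded pedigree-aware
    simulator generates joint-called trio cohorts with Mendelian
    transmission, de novo events, genotype errors, parental dropout,
    per-sample read support, Ti/Tv-controlled SNVs and GC-biased
    coverage tracks, together with a truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
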