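Package: morphdiff
Title: Polymorphism and Fixed-Difference Analysis of Two-Population EST Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: SNP discovery and divergence analysis for low-depth expressed
    sequence tag (EST) data from two populations of one species. Reads are
    quality-trimmed, Q20-masked and realigned to contig references with a
    stringent local aligner; per-site allele counts are filtered through a
    binomial sequencing-error model with a minor-allele-frequency floor;
    sites are classified as shared, divergent or one-population polymorphisms
    or as fixed inter-population differences. Fixed differences are projected
    onto coding frames via outgroup protein alignment, classified as
    synonymous, non-synonymous or nonsense, polarized by outgroup parsimony,
    and scored as radical or conservative under a six-class physicochemical
    amino-acid scheme. Gene sets carrying radical substitutions are tested
    for annotation enrichment with Fisher's exact test and plain
    hypergeometric tests. A synthetic-data generator with a recorded truth
    set makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
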