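Package: nanoJunction
Title: Detection of Inverted-Duplicate Junction Sequencing Failures in
    Nanopore Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterizing the systematic
    base-calling failure that affects nanopore long reads spanning
    inverted-duplicate DNA junctions. Provides sample-wide phred
    statistics and low-phred region detection with expansion and
    bounded/unbounded classification; split-read calling of
    inverted-duplicate junctions from opposite-strand supplementary
    alignments with greedy boundary-pair resolution and read-depth
    enrichment; raw-signal analysis of current uplift and per-segment
    samples-per-base translocation-rate estimates; rank correlation of
    preceding-region versus low-region lengths; and a deterministic
    synthetic-data generator that emulates the failure phenotype
    (collapsed phred scores, missed bases, elevated current, reduced
    sampling rate) for end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    Rsamtools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cigar.R'
    'core_io.R'
    'junctionscan.R'
    'nanoJunction-package.R'
    'phredscan.R'
    'plots.R'
    'report.R'
    'rolling.R'
    'simdata.R'
    'squiggle.R'
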