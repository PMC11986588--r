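Package: helicap
Title: Helitron Gene-Capture Detection and Allopolyploid Epigenomic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene-capture events carried by Helitron-superfamily
    transposable elements from genome annotations and sequence, using affine-gap
    Smith-Waterman local alignment with Karlin-Altschul E-value screening,
    donor-gene assignment by highest bit score, and single/multiple capture
    classification. Characterizes events (UTR/CDS composition, positional
    classes, per-Mb density, pseudogene overlap), computes Nei-Gojobori Ka/Ks
    for homoeologous gene pairs, and quantifies 24-nt siRNA abundance (RPM),
    CG/CHG/CHH methylation and expression (TPM) of donor genes and
    gene-capturing elements across an allopolyploidization series (in-silico
    hybrid, resynthesized and natural allopolyploid). Ships a seeded synthetic
    data generator producing a two-subgenome genome with planted captures so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
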