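Package: ervscan
Title: Screening Gene Neighborhoods for Endogenous Retrovirus-Like Open
    Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate endogenous retrovirus (ERV) sequences in the
    genomic neighborhood of stress-induced genes. Starting from a processed
    expression matrix, genes up-regulated under a hypoxia-mimetic treatment
    are called with fold-change, intensity and replicate-concordance
    thresholds; the 2 Mbp window around each candidate gene is extracted
    from a genome assembly; open reading frames of at least 1 kb are
    enumerated on both strands and translated; translated ORFs are scored
    against a retroviral protein database with exact Smith-Waterman local
    alignment under affine gap penalties and Karlin-Altschul E-value
    statistics, with a two-tier E-value classification; and qPCR validation
    data are quantified by the 2^-ddCt method with median-of-samples
    calibration. A synthetic-data module generates genomes with planted
    env-like ORFs, expression matrices with planted up-regulated genes and
    Ct tables with known fold changes, so the whole chain is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
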