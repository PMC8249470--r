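Package: pingpongr
Title: Ping-Pong Signature and Small RNA Library Analysis for piRNA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analysis of ovarian small RNA
    libraries centred on the piRNA ping-pong amplification signature.
    Implements count-weighted 5' overlap partner histograms with the
    ping-pong fraction at a 10 nt overlap, 1U/10A nucleotide bias
    statistics, read classification with miRNA-normalized transposon and
    genomic-window abundance (including reads-per-million filters and
    fold changes against a control genotype), an edit-distance read to
    transposon-consensus matcher, exponential recovery fitting for FRAP
    experiments, and a synthetic small RNA library generator that plants
    a parameterized ping-pong structure with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
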