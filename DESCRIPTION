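Package: dichrom
Title: Single-Molecule Dichromatin Analysis of Centromeric Fiber-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-molecule chromatin fiber sequencing
    (Fiber-seq) data over centromeric satellite arrays: calling centromere
    dip regions (CDRs) from aggregate CpG methylation with a stepped-window
    percentile algorithm, per-fiber di-nucleosome and accessible-patch
    (large MSP) metrics with observed versus expected patch spacing,
    per-fiber Fourier periodograms of m6A patterns for chromatin repeat
    length estimation, CENP-B box motif scanning with per-molecule CpG
    stratified footprint scoring, and a synthetic fiber generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
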