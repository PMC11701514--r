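Package: saberseq
Title: Signal-Activated Barcode Editing Recorder Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for signal-recording CRISPR barcodes read out by
    single-cell and bulk amplicon sequencing. Models a four-target Cas9 barcode
    array, simulates signal-dependent multi-round editing with intra- and
    inter-site deletions, calls per-cell consensus alleles from 10x-style
    paired reads (affine-gap alignment, mappability filtering, UMI and cell
    consolidation, whitelist matching), and computes signal-tracing statistics:
    edited fractions, deletion spectra and site-link matrices, per-cluster
    exact binomial divergence and detection-bias tests, and tissue-normalized
    edited fractions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
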