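Package: sixmaQC
Title: MeDIP-Seq Guided Quality Control of SMRT 6mA Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Filters false-positive N6-methyladenine (6mA) calls from SMRT
    sequencing kinetics without whole-genome-amplification control data.
    Strictly filtered calls lying inside enriched MeDIP-seq peaks form a
    conservative set; a random sample of their IPD ratios yields a
    lower-confidence-bound threshold on the mean, which is then applied to
    the genome-wide call table. Motif-based proportion statistics quantify
    how thresholding changes the motif and non-motif composition of the
    call set, and a synthetic-data generator with ground truth emulates
    prokaryote-like (motif-driven) and eukaryote-like (weakly motif-driven)
    methylation regimes so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
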