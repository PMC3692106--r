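Package: promdesign
Title: Data-Driven Design of Synthetic Plant Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing synthetic plant promoters from published
    expression and cis-regulatory motif data. Mines tissue-panel microarray
    tables and diurnal time series for genes with extreme or strongly
    rhythmic expression, retrieves the cis-regulatory motifs annotated on
    those genes, and arranges the motifs on a transcription-start-site
    relative design canvas with natural-position placement, stacking with
    fixed spacing, overlap conflict resolution, baseline fill-in, and a
    replayable edit log. Includes deterministic synthetic-data generators
    with planted ground truth for end-to-end testing, and a command-line
    front-end tying mining to design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
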