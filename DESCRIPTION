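Package: biofilmDGE
Title: Digital Gene Expression Analysis of Yeast Biofilm Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tag-counting digital gene expression (DGE) pipeline for
    comparing Saccharomyces cerevisiae biofilm cells against free cells
    across staged biofilm development. Implements read quality filtering,
    RPKM quantification, the Audic-Claverie two-library Poisson exact test
    with false discovery rate control, differential expression calling,
    hypergeometric pathway over-representation analysis, and qPCR
    concordance by the 2^-ddCt method. Ships a seeded synthetic-data
    generator that emulates staged biofilm count libraries with planted
    fold changes, annotation maps, contaminated FASTQ reads, and Ct tables
    so the full pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
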