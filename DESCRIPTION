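Package: tertdup
Title: ETS-Creating Tandem Duplications in the TERT Core Promoter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating tandem-duplication insertion variants in the
    TERT core promoter and asking whether they mimic the recurrent hotspot
    point mutations. Implements a c.-position to hg19 genomic coordinate map
    anchored at the TERT ATG, tandem-duplication detection and left-aligned
    normalization of insertion variants, equivalence-classing of duplication
    windows by byte identity of the resulting variant sequence, GGAA (ETS)
    motif scanning with native versus de novo origin assignment, helical-phase
    spacing analysis at 10.5 bp per turn, an ordinal promoter-activity
    classifier with a simulated dual-luciferase readout, cohort table
    validation and GGAA-insertion screening, and multiregion tumor clonality
    reconstruction by exhaustive ordinary-least-squares minimum-evolution
    trees on Manhattan distances of binary mutation calls. A synthetic-data
    module generates reference windows, insertion screens and multiregion
    mutation matrices with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
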