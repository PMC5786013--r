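Package: chains4d
Title: Automated NMR Resonance Assignment from 4D HCNH TOCSY and NOESY Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps amide spin systems (amino-acid index groups, AAIGs) from 4D
    HC(CC-TOCSY(CO))NH and 4D HMQC-NOESY-HSQC peak lists onto a protein
    sequence and emits near-complete backbone and sidechain 1H/13C/15N
    chemical-shift assignments in XEASY format.  Amino-acid types are
    predicted from correlated 13C-1H chemical shifts with two-dimensional
    Gaussian kernel density maps and a Bayesian posterior; sequential
    connectivities are assembled into chains and contigs by overlap-layout-
    consensus, aligned to the sequence with a BLOSUM90-scored ungapped
    Needleman-Wunsch fit, and refined over iterations of decreasing chain
    length.  Missing sidechain assignments are completed from common NOEs
    shared between sequential amides.  A seeded synthetic-data generator
    produces ground-truth-labelled peak lists for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
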