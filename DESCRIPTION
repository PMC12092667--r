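Package: beditscan
Title: Simulation and Analysis of FACS-Sorted CRISPRi Screens for Cytosine
    Base-Editing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of a reporter-coupled CRISPRi
    screen that dissects cytosine base-editing outcomes: simulation of editing
    amplicons and sorted-population sgRNA count matrices with known ground
    truth; allele-level quantification of editing outcomes (C-to-T, C-to-G,
    C-to-A, dual and mixed edits, indels) from amplicon reads via global
    affine-gap alignment; screen enrichment testing with median-of-ratios
    normalization, negative-binomial sgRNA tests and alpha robust rank
    aggregation (alpha-RRA) gene scores with permutation p-values; and the
    arrayed-validation statistics used to confirm hits (z-scores against
    non-targeting controls, adjusted z-scores with significance tiers, fold
    changes, relative outcome fractions, rescue deltas, and delta-delta-Ct
    expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
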