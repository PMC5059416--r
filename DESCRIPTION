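Package: pickedfdr
Title: Semi-Supervised PSM Rescoring and Picked Protein False Discovery Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical post-processing for shotgun proteomics search results.
    Rescores peptide-spectrum matches (PSMs) with an iterative semi-supervised
    linear support vector machine under three-fold cross-validation, including a
    downsampled (random-subset) training mode for very large PSM collections.
    Estimates target-decoy q-values, posterior error probabilities and empirical
    p-values at the PSM, peptide and protein levels. Performs in-silico tryptic
    digestion, groups proteins by their theoretical peptide sets, scores protein
    groups by four inference methods (best peptide, two-peptide rule, product of
    peptide-level PEPs, Fisher's method) and controls protein-level FDR with the
    picked target-decoy strategy. Ships a sample/entrapment calibration benchmark
    built on a seeded synthetic proteome and PSM generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
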