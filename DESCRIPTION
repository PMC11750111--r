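Package: phosflow
Title: Time-Course TMT Phosphoproteomics Analysis with Starvation-Corrected Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed (TMT) time-course phosphoproteomics
    of fission yeast sexual differentiation. Provides per-replicate median
    normalization, missing-value filtering, exact-duplicate collapse and
    re-expansion of redundant phosphosites, empirical-Bayes moderated linear
    models with difference-of-differences (starvation-corrected) contrasts,
    Benjamini-Hochberg adjustment and significance-class labels, monotone
    profile clustering, phosphosite-protein covariation regression,
    kinase-substrate Fisher enrichment, sequence-window motif frequency
    matrices, microscopy mating/fusion efficiency metrics, and a seeded
    synthetic-data generator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    readxl,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
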