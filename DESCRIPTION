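Package: flavoromics
Title: Taste and Odor Activity Screening for Cooking-Time Flavoromics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for flavoromics studies of cooked foods that
    report group-mean compound tables: taste activity values (TAV) for free
    amino acids and 5'-nucleotides, relative odor activity values (ROAV) for
    GC-IMS volatile peak tables with monomer/dimer handling, semi-quantitative
    normalization and chemical-class aggregation, hand-rolled OPLS-DA with VIP
    scores and label-permutation validation, Pearson taste-odor correlation
    screening with hierarchical clustering, and a seeded synthetic-replicate
    generator that emulates group-structured mean +/- SD measurements so every
    downstream stage is testable without replicate-level raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
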