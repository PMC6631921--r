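Package: varvote
Title: Consensus Pathogenicity Calling and Neutral-Variant Benchmarking
    for Missense Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Thresholds per-variant predictor scores (an SVM pathogenicity
    probability, a FoldX folding free-energy change, and a PolyPhen-2
    damage probability) into deleterious/neutral calls and aggregates them
    into a four-level consensus category. Builds ortholog-derived neutral
    benchmark variant sets from pairwise alignments using conserved-flank,
    gap-proximity, structural contact-conservation and sequence-identity
    filters, with residue contact maps computed from PDB coordinates.
    Benchmarks predictors against labelled variant sets with the standard
    six binary-classification statistics (sensitivity, specificity, PPV,
    NPV, accuracy, balanced accuracy). Ships transcribed published score
    tables for SERPINA1 (alpha-1 antitrypsin) variants as worked fixtures
    and seeded synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
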