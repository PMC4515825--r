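Package: thiamintargets
Title: Discovery of Non-Coenzyme Thiamin-Binding Proteins by Pattern
    Scanning, Structural Validation and Inhibition Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying candidate thiamin
    (vitamin B1) binding proteins beyond the coenzyme role of thiamin
    diphosphate. Implements a PROSITE-dialect sequence pattern parser and
    scanner; derivation of binding patterns from protein-ligand complex
    structures with backbone-conformation (Ramachandran) and
    active-site-proximity validation; enzyme inhibition kinetics with
    Lineweaver-Burk diagnostics and AICc-based mechanism classification
    (competitive, non-competitive, uncompetitive, mixed) with Ki
    estimation; affinity-proteome yield accounting, known-binder
    fractions and one-sided Fisher term enrichment with
    Benjamini-Hochberg adjustment; and seeded synthetic-data generators
    (planted-motif sequences, ideal backbones with placed ligands, noisy
    initial-rate datasets, proteome/annotation tables) providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
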