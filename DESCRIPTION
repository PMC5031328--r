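Package: pdzthread
Title: Template-Based Modeling and Contact-Potential Scoring of PDZ-Peptide
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based analysis of PDZ domain peptide recognition.
    Builds peptide-bound PDZ models by rigid grafting of peptides from holo
    templates onto apo domain structures (sequence-alignment-guided Kabsch
    superposition), threads query peptide sequences through template
    geometry, and scores binding with a residue-pair statistical contact
    potential summed over interface contacts within 4.5 Angstroms. Includes
    the benchmarking machinery for binder/non-binder classification
    (per-threshold ROC and precision-recall curves, trapezoid AUC, balanced
    resampling for imbalanced data, confusion statistics at a score cutoff),
    PDmapper-style matching of peptides against proteome C-termini with
    mismatch allowance and a hydrophobic C-terminus constraint, mapping of
    single amino-acid polymorphisms onto domain ranges, and deterministic
    synthetic-fixture generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
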