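Package: dockjury
Title: Consensus Quality Assessment of Protein Quaternary Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores, ranks and annotates predicted models of protein
    complexes (quaternary structures) without requiring the native
    structure, using a consensus ("jury") approach: each model in a pool
    is compared against every other model with a panel of assembly
    similarity metrics (lDDT, TM-score, GDT_TS, CAD, QS-score, DockQ-wave,
    and patch-based local interface scores), and per-model quality is the
    aggregate of those pairwise comparisons. Also provides reference-based
    scoring of a model against a native structure, stoichiometry parsing
    and template-frequency voting, chain mapping for homo- and
    hetero-oligomers, CASP QA (QMODE1/QMODE2) file input/output, PDB
    reading/writing with per-residue score annotation in the B-factor
    column, an assessor-style evaluation layer (correlations, ROC AUC,
    top-1 loss and composite totals), and a seeded generator of synthetic
    reference complexes and perturbation-graded decoy pools for testing
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
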