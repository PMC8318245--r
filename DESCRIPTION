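Package: ssepssm
Title: Secondary-Structure-Element Position-Specific Scoring Matrices for
    Protein Secondary Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds position-specific scoring matrices over secondary
    structure element (SSE) alphabets instead of amino acids. A query
    protein is searched against a structure-annotated target set, hit
    alignments are SSE-transformed, and identity-weighted code occurrences
    are normalized into a position propensity matrix and log2 log-odds
    PSSM, with a Henikoff-style pseudocount fallback driven by a
    BLOSUM-style SSE substitution matrix built from aligned SSE corpora.
    Profiles become sliding-window machine-learning features for a
    bootstrap-vote ensemble of per-residue classifiers, and predictions
    are scored with the field's full metric suite: Q3/Q8, the 1999-revision
    segment overlap measure (SOV3/SOV8), boundary and internal accuracy,
    and pairwise misclassification rates. A seeded synthetic protein-family
    generator makes the whole pipeline testable without any database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    nnet,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
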