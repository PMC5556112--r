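Package: pudti
Title: Drug-Target Interaction Screening with Positive-Unlabeled Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens candidate drug-target interactions (DTIs) when only
    positive interactions are recorded and no experimentally validated
    negatives exist. Implements reliable-negative extraction from unlabeled
    drug-target pairs by AND-consensus of a spy-based naive Bayes/EM
    classifier and a Rocchio prototype classifier, soft similarity weighting
    of the remaining ambiguous pairs from local (micro-cluster) and global
    (prototype) cosine similarities, and a similarity-weighted support
    vector machine whose per-sample slack penalties reflect those weights.
    Also provides protein descriptors (pseudo amino acid composition,
    bi-gram position-specific scoring matrix features, domain indicator
    vectors), a discriminant-ability feature filter, a pairwise
    cross-validation protocol with positive-unlabeled splits, and a seeded
    synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071
Config/testthat/edition: 3
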