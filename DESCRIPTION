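Package: funpairs
Title: Pair-Based Assessment of Protein Function Annotation Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ontology-blind benchmarking harness for protein function
    annotation methods. Functionally similar "sibling" protein pairs are
    labeled from structure (TM-score) and functional (Siamese-network, SNN)
    similarity gates; per-protein annotation predictions in any vocabulary
    (GO, EC, Pfam, ortholog groups, embeddings) are converted into pairwise
    similarity scores; and methods are scored with a threshold-sweep metric
    suite (F1max over joint prediction/similarity thresholds, recall-weighted
    score separation, recall under a predicted-positive budget, PR/ROC AUC)
    against resampled positive-versus-unlabeled pair sets, with empirical
    random baselines and per-bin Fisher enrichment reports. Includes ontology
    parsing with information-accretion weighting and a synthetic-data
    generator with planted function clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
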