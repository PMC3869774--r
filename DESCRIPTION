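Package: sagetime
Title: Longitudinal SAGE Tag-Count Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved SAGE/SuperSAGE tag-count
    transcriptomes, as used to profile aging cultures of the filamentous
    fungus Podospora anserina over seven age stages. Provides tags-per-million
    normalization, missing-value filtering and per-profile standardization,
    Audic-Claverie pairwise differential-expression tests between sequencing
    libraries, significance smoothing of expression time courses, fuzzy
    c-means clustering with Xie-Beni cluster-number selection, detection of
    continuously up- or down-regulated profiles by correlation with
    chronological age, GO annotation transfer from homology hits with
    hypergeometric over-representation tests and enrichment-map export
    (GMT/GraphML), and a two-universe permutation null for cross-study
    gene-set overlaps. Includes a seeded synthetic-data generator producing
    ground-truth-labeled count matrices, annotation tables and homology hit
    files so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
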