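Package: dddclust
Title: Digital Differential Display and GO Semantic-Similarity Clustering of
    Tissue-Specific Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico prioritisation of tissue-specific biomarker panels from
    expressed sequence tag (EST) library counts. Implements digital
    differential display (pooled transcript frequencies, signed fold changes
    and two-sided Fisher exact tests), subtractive candidate filtering with a
    provenance log, Wang graph-based Gene Ontology semantic similarity with
    best-match-average gene scores, hierarchical clustering of similarity
    profiles with multiscale-bootstrap approximately unbiased (AU) cluster
    p-values, and assembly of biomarker panels from supported clusters.
    Includes readers and writers for OBO, GAF, gene-list and tab-separated
    count formats, and a seeded synthetic-data generator (multinomial EST
    libraries, toy ontologies, planted gene groups) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    jsonlite
Config/testthat/edition: 3
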