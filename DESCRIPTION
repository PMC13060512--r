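Package: rdrkit
Title: Knowledge-Based Rare Disease Recognition from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A local, deterministic toolkit for rare disease recognition from
    clinical text. Builds a computable disease-knowledge layer from
    schema-guided markdown disease profiles and a clinical concept lexicon
    (deterministic dictionary matching over four semantic groups); screens
    patients with a two-stage pipeline (BM25 sparse retrieval plus dense
    embedding similarity fused by reciprocal rank fusion, then
    knowledge-boosted reranking of the top candidates); selects among
    multiple knowledge sources with a Spearman-gated ensemble; and
    discriminates cases from controls using longitudinal note streams via
    symptom-week coding, co-occurrence pair features, symptom importance
    scores and stratified out-of-bag bootstrap evaluation of a logistic
    classifier. Ships quality metrics for knowledge profiles (SMOG
    readability, reference typing, concept coverage, Jaccard overlap,
    weighted kappa) and synthetic-data generators so every stage is testable
    without external models or protected health data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
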