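Package: medsom
Title: Self-Organizing Maps of Annotated Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-trains square-grid self-organizing maps (SOMs) on sparse
    binary controlled-vocabulary annotation vectors of article corpora, with
    topographic-error model selection and domain/non-domain node
    classification.  Provides the downstream interpretive layer used to
    validate such maps against expert-curated reference sets: best-matching-
    unit projection, k-means clustering of grid positions with elbow-based
    selection of the cluster count, cluster-defining vocabulary terms and
    exemplar articles, 95% normal ellipses, and cross-edition overlap
    summaries.  Includes fuzzy bibliographic reference matching against a
    local record set, edition-level citation persistence statistics, and a
    seeded synthetic-data generator (planted-topic corpora, hierarchical
    vocabularies, multi-edition reference lists) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
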