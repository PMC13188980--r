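Package: litfuse
Title: Hybrid Lexical-Semantic Retrieval for Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained hybrid search library for bibliographic
    records in the PubMed/MEDLINE XML dialect.  Documents are scored by
    per-publication-year Okapi BM25 shards and by embedding cosine
    similarity against a pluggable text encoder; the two signals are
    min-max normalized and fused with a sigmoid-adaptive weight into a
    single bounded relevance score used for thresholded ranked
    retrieval.  Includes result filtering, facet summaries, CSV/BibTeX
    export, an information-retrieval evaluation harness (NDCG, MAP, MRR
    at rank cutoffs, mean query-result cosine with relevance
    bucketing), and a deterministic synthetic-corpus generator with
    test encoders so the whole pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
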