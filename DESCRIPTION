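Package: semsuggest
Title: Semantic Query Suggestion from Corpus-Trained Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tool set for building semantic query-suggestion services for
    life-science text search. Provides corpus preprocessing with
    collocation-based phrase mining, word-embedding training (continuous
    bag-of-words and skip-gram architectures with hierarchical softmax over
    a Huffman tree), a compact binary model format, top-k alternative-query
    ranking by cosine similarity, a JSON-over-HTTP suggestion service, and
    an ontology-based evaluation of suggestion quality using Resnik and Lin
    information-content similarity over OBO ontologies. Includes synthetic
    corpus and toy-ontology generators with planted structure so that the
    whole stack can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
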