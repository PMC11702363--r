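Package: kgqa
Title: Schema-Guided Question Answering over Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for answering natural-language questions over property
    graphs of drugs, genes, mutations, diseases and clinical trials. Questions
    are decomposed into a structured frame (head entities, tail type, tail
    attribute constraints), candidate relational paths between the head and
    tail entity types are enumerated on the type-level schema graph by
    breadth-first search, the optimal path is selected by cosine similarity
    between embeddings of the question and each verbalized path, a
    Cypher-style linear query is generated and executed against the graph,
    retrieved relational chains are pruned against the frame, and a grounded
    answer is composed from the surviving chains. Includes a four-category
    benchmark generator (one-hop, multihop, intersection, attribute
    questions) with traversal-derived gold answers, and ROUGE-L plus
    exact-set-match evaluation. All backends (entity extraction, embedding,
    answer composition) are deterministic by default and pluggable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
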