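Package: chemkgqa
Title: Hybrid Knowledge Graph Embedding Question Answering for Chemistry Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Embedding-based question answering over chemistry knowledge graphs.
    Implements five translation/bilinear knowledge-graph embedding methods
    (TransE, TransEA, TransR, TransRA, ComplEx) with joint numerical-attribute
    embedding, implicit multihop relation derivation for deep ontologies, an
    embedding-based QA workflow with fuzzy entity linking and two-round
    numerical filtering, cross-ontology score alignment for merging answers
    from independently trained embedding spaces, a filtered/unfiltered
    link-prediction evaluation harness, and a synthetic knowledge-graph
    generator with planted geometric structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
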