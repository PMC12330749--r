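Package: beltograph
Title: Literature-Mined Molecular Interaction Knowledge Graphs in BEL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts scientific text into molecular-interaction knowledge
    graphs encoded in the Biological Expression Language (BEL). Provides a
    parser, canonical serializer and validator for a causal BEL subset;
    ingestion of BioC-style full-text XML and local text or markdown files
    into paragraph lists; pluggable named-entity grounding against
    standardized namespaces (HGNC, GO, CHEBI); LLM-driven statement
    extraction behind a swappable backend contract so the whole pipeline
    runs offline with deterministic stubs; deduplicated property-graph
    construction with CX2 (Cytoscape Exchange v2) import and export and an
    NDEx client contract; a component-level statement-comparison scorer
    with best-match pairing, agreement aggregation and an LLM-as-judge
    rubric; and GraphRAG-style k-hop neighborhood retrieval that embeds
    subgraphs into prompt contexts. A command-line entry point wires the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
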