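# beltograph

Literature-mined molecular interaction knowledge graphs in the Biological
Expression Language (BEL), for R.

Building a knowledge graph from publications normally means manual
curation. LLMs can extract causal biology from text, but their output has
to be forced into a formal representation, grounded in standard
identifiers, and checked before it is a graph anyone should trust.
`beltograph` is that machinery: it parses and validates a causal BEL
subset, ingests full-text articles (BioC-style XML or local files),
grounds entity mentions through a pluggable grounder, drives statement
extraction through a swappable LLM backend contract (so the entire
pipeline runs deterministically offline), builds deduplicated property
graphs, and exchanges them with the Cytoscape ecosystem as CX2 JSON. It
also ships the evaluation machinery for comparing statement sets and a
GraphRAG-style neighborhood retriever that feeds subgraphs into prompt
contexts.

It is aimed at computational biologists who want topic-focused interaction
networks from specific papers, and at tool builders who need a tested BEL
and CX2 layer in R.

## The core representation

A BEL statement is subject–predicate–object over functionally composed
terms grounded in standard namespaces:

```
act(p(HGNC:AKT1), ma(GO:"kinase activity")) directlyIncreases
    p(HGNC:HSF1, pmod(Ph, Ser, 326))
```

— the kinase activity of AKT1 directly increases HSF1 phosphorylated at
Ser-326. Supported functions: `p g r a complex bp path act deg tloc`;
modifications `pmod ma frag loc`; relations `increases decreases
directlyIncreases directlyDecreases association regulates`.

Statement sets are compared component-wise: subject, relation and object
are matched on canonical forms, each matching component earns its weight
(relation 0.4, subject 0.3, object 0.3 by default), and the total score is
the sum — 1 for identical statements, 0 for fully disjoint ones, 0.4 when
only the relation agrees. Namespace-only agreement is tracked separately
and unscored.

## Worked example

The packaged fixtures — a BioC-style article, a mini-lexicon, a scripted
extraction backend — run the whole pipeline offline:

```r
library(beltograph)

s <- parse_bel(paste(
  'act(p(HGNC:AKT1), ma(GO:"kinase activity")) directlyIncreases',
  "p(HGNC:HSF1, pmod(Ph, Ser, 326))"))
print(s)
#> <bel_statement> act(p(HGNC:AKT1),ma(GO:"kinase activity")) directlyIncreases p(HGNC:HSF1,pmod(Ph,Ser,326))

doc <- filter_paragraphs(fetch_article("PMC0000001", bioc_client_fixture()))
run <- extract_document(doc, dictionary_grounder(),
                        stub_backend_from_file(fixture_stub_script_path()))
g <- statements_to_graph(run$records, name = "fixture network")
print(g)
#> <knowledge_graph> 'fixture network': 6 node(s), 4 edge(s)

a <- parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)")
b <- parse_bel("p(HGNC:TP53) increases p(HGNC:MDM2)")
print(compare_statements(a, b))
#> <comparison_result> total=0.40 (subject=FALSE relation=TRUE object=FALSE)

sub <- neighborhood(
  merge_graphs(list(fixture_graph_dna_damage(), fixture_graph_metabolism())),
  neighborhood_query(c("SIRT1", "PARP1")))
print(sub)
#> <knowledge_graph> 'merged network': 9 node(s), 7 edge(s)
```

The 6 nodes / 4 edges are the deduplicated terms and triples of the four
scripted extractions (the AKT1 activity node is distinct from plain
`p(HGNC:AKT1)` by design); the 0.40 comparison score is the relation
sub-score earned when only the predicate matches; the final 9-node
subgraph is the 1-hop neighborhood of SIRT1 and PARP1 in the merged
DNA-damage + metabolism toy network, the bridge that connects the two
processes through NAD⁺.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/exec/beltograph extract --pmcid PMC0000001 --fixture \
    --backend stub --script inst/extdata/fixture_stub_script.json \
    --out results.json --cx2 network.cx2
```

`network.cx2` loads directly into Cytoscape / Cytoscape Web, and
`upload_network()` sends it through an NDEx-style client contract.

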