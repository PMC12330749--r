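---
title: "From literature text to BEL knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From literature text to BEL knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltograph)
```

## The problem

Curating molecular-interaction knowledge graphs from publications is slow
and expensive, and classical sentence-level text mining misses
relationships that require context across sentences or background
knowledge. Large language models can extract such relationships, but their
output must be constrained into a formal, computable representation and
checked against standard identifiers before it can be trusted as a graph.

`beltograph` implements that pipeline around the Biological Expression
Language (BEL). BEL encodes causal and correlative biology as
subject–predicate–object statements over functionally composed terms: the
statement

```
act(p(HGNC:AKT1), ma(GO:"kinase activity")) directlyIncreases
p(HGNC:HSF1, pmod(Ph, Ser, 326))
```

says that the kinase activity of the AKT1 protein directly increases the
amount of HSF1 protein phosphorylated at serine 326. Entities are grounded
in standard vocabularies (HGNC for genes, GO for processes and activities,
CHEBI for chemicals), which is what makes the resulting graphs mergeable
and queryable.

## The BEL subset and its grammar

The package handles a causal BEL subset: term functions
`p, g, r, a, complex, bp, path, act, deg, tloc`, modifications
`pmod, ma, frag, loc`, and relations `increases, decreases,
directlyIncreases, directlyDecreases, association, regulates`. BEL itself
is larger (reactions, fusions, translocation arguments); this subset covers
the statements a causal-interaction extractor produces, and the
vocabularies are extensible through `options(beltograph.functions)`,
`beltograph.relations` and `beltograph.namespaces` so a deployment can
widen them without code changes.

The parser is a hand-written recursive-descent parser with typed error
conditions (`bel_syntax_error` with a character offset,
`bel_unknown_function`, `bel_unknown_relation`, `bel_unknown_namespace`).
The serializer emits one canonical form: no spaces after commas, entity
before inner terms before modifications, double quotes exactly when a name
contains characters outside `[A-Za-z0-9_]`, namespaces uppercased. Two
design points deserve note:

* **Canonical string as identity.** Structural equality of terms is
  implemented independently (`bel_equal()`, a recursive field comparison)
  and the test suite checks that canonical-string equality coincides with
  it over hundreds of random term pairs. This lets the canonical string
  serve as the node-identity key during graph construction.
* **Typographic tolerance.** Typeset text often fuses quoted names
  (`GO:"kinaseactivity"`) or uses curly quotes; the tokenizer accepts both
  and preserves the quoted text verbatim, normalizing only the quoting
  style.

Structural validation (function arities, `pmod` argument rules, a maximum
nesting depth of 4) and allow-list validation return violations as data —
`{code, path, message}` records — rather than exceptions, because
downstream review workflows need to see invalid statements, not lose them.

## Ingestion and grounding

Articles arrive either as BioC-style XML (passages with `section_type`
infons and entity-annotation spans) through an injected article-service
client, or as local text/markdown split on blank lines with heading-derived
section labels. Text is Unicode-normalized and control characters are
stripped; annotation offsets are relocated if normalization shifts them, so
the substring invariant `substr(text, start+1, end) == matched_text` always
holds on stored paragraphs.

Paragraph filtering defaults to a deterministic rules mode that drops
blocklisted sections (references, acknowledgments, funding, author
contributions — configurable, since full-text services do not document
which section types carry extractable content); an `llm` mode delegates the
keep/drop decision to a backend for pipelines that prefer model triage.

Grounding is pluggable. The packaged offline grounder is an exact and
case-insensitive whole-word dictionary over a mini-lexicon (a dozen HGNC
symbols, a few GO and CHEBI names) — enough to run the whole pipeline with
no network. Exact matches score 1.0 and case-insensitive matches 0.8, a
deliberate ranking so that overlap resolution (highest score, then longest
span, then earliest start) prefers verbatim mentions. A live
grounding-service client satisfies the same `ground(text)` contract;
grounding quality is known to dominate end-to-end quality, which is exactly
why the grounder is a swappable seam rather than a hard dependency.

## Extraction behind a backend contract

Every LLM call goes through a backend object (`complete`, `repair`,
`keep`, `judge`). The deterministic scripted stub makes the pipeline
bit-reproducible for tests and demonstrations; a live API client would
implement the same contract. The extraction prompt contains a BEL syntax
guide with examples, the paragraph, and the allow-list rendered one
`NAMESPACE:ID  (name)` line per entry — constraining the model to
pre-grounded identifiers is the main defense against hallucinated
entities.

Three policies are fixed here and worth recording:

* **One repair round-trip.** A statement that fails to parse is sent back
  once with the parser error attached; if it still fails it is quarantined
  with its raw payload. One round prevents unbounded repair loops, and the
  accounting invariant `raws = records + quarantined` is tested.
* **Retain-with-violation.** Statements citing entities outside the
  allow-list are kept and flagged (`ungrounded entity`), not dropped, so a
  reviewer can see what the extractor believed.
* **Evidence fidelity at 0.9.** The claimed evidence sentence must match
  some paragraph sentence at ≥ 0.9 normalized similarity
  (case/whitespace-insensitive Levenshtein, via `utils::adist`); below
  that a `paraphrased evidence` violation is recorded. The threshold
  tolerates tokenization noise while catching invented evidence; it is a
  parameter of `extract_paragraph()`.

## Graph construction and CX2

`statements_to_graph()` assigns one node per distinct canonical term and
one edge per distinct (subject, relation, object) triple, evidence lists
merged, ids in first-appearance order from 0. Node identity is the
canonical BEL term string, so `p(X)` and `act(p(X))` are distinct nodes —
BEL semantics distinguish an entity from its activity, and collapsing them
would erase that. Edge-per-evidence is available as a flag
(`collapse_edges = FALSE`) for workflows that want one edge per extraction.

CX2 (Cytoscape Exchange v2) is the interchange surface: the writer emits
the aspect list (`CXVersion`, `attributeDeclarations`,
`networkAttributes`, `nodes`, `edges`, `status`) with declared attribute
types and a stable key order, so output is byte-stable and a golden file
can be compared exactly. Edge evidence is stored as three parallel list
attributes (`evidence`, `source`, `paragraph`) and zipped back on read,
making read∘write the identity on the package's own output; the reader is
tolerant of foreign CX2 (nodes without a `bel` attribute degrade to
label-only nodes). Upload is a pass-through of the CX2 payload to a client
contract with `save_network()`; tests use a recording mock.

## The comparison scorer

To compare two statement sets (e.g. against another extraction system
converted to BEL), statements sharing an evidence text are paired and each
pair scored component-wise on canonical forms: subject term, relation,
object term. Each matching component earns its weight and the total is
their sum. The relation carries weight 0.4; the remainder is split evenly
between subject and object (0.3 each) so that identical statements score
exactly 1 and fully disjoint ones 0. The subject/object split is a
package choice — only the relation sub-score and the maximum are pinned by
the scoring scheme this reproduces — and the weights are a configurable
table.

Namespace-only agreement (same vocabulary for the subject or object
primary entity, different term) is tracked in separate booleans and never
scored: it measures a weaker, systematically different kind of agreement
and is reported separately by `aggregate_agreement()`, which emits counts,
fractions and percentages rounded to one decimal. With zero pairs the
fractions are `NA` — undefined, not zero. Best-match pairing is an argmax
over candidate scores with first-wins tie-breaking, and the suite checks it
against a brute-force oracle.

Semantic similarity beyond component equality goes through the
LLM-as-judge rubric (Good = same relationship; Medium = related but
differing in specificity; Bad = different relationships). The judge always
goes through the backend contract; an out-of-vocabulary answer is a typed
error rather than a silent coercion, and CI uses the scripted stub.

## GraphRAG retrieval

`neighborhood()` retrieves the k-hop neighborhood of query genes: seeds
are matched by node label or entity identifier (case-insensitive, exact
token — substring matching would conflate gene families), traversal is
undirected by default because a gene's functional neighborhood includes
both regulators and targets (a directed mode is a flag), and the result is
the induced subgraph. Traversal delegates to igraph's ego expansion; the
test suite checks it against an independent breadth-first search and the
hop-monotonicity property. `merge_graphs()` unions graphs with node dedup
by canonical term and edge dedup by triple, recording per-node/per-edge
provenance.

`build_context()` embeds the retrieved subgraph as CX2 JSON into a prompt
along with the question and an instruction block toggled by the
internal-knowledge flag. `run_demo()` executes the seven standard
variations — {graph A, graph B, merged} × {with, without internal
knowledge} plus a no-graph baseline — over two packaged toy graphs: a
DNA-damage-response graph and an NAD⁺-metabolism graph that share bridge
nodes (SIRT1, PARP1, NAD⁺), so the merged case visibly connects the two
themes. Both toy graphs are synthetic, built in code from hand-written BEL
statements.

## What the fixtures emulate — and what they do not

The bundled fixture article (BioC-style XML, six passages including an
empty one and a references section), the mini-lexicon, and the scripted
stub backend emulate the *structure* of the real inputs: paragraph
segmentation with section types, annotation spans with offsets, grounding
responses with scores, structured extraction responses with evidence
sentences. They do not emulate the hard parts of real data: ambiguous
entity mentions, cross-sentence reasoning, model hallucination rates, or
the breadth of a real lexicon. Passing tests therefore demonstrate that
the machinery around the model — parsing, validation, provenance,
deduplication, export, scoring, retrieval — is correct and deterministic;
they say nothing about the extraction quality of any particular live
model, which must be evaluated with human review on real articles.

## Numerical and degenerate-input choices

* Comparison weights must sum to 1 (checked to 1e-9); scores are exact
  sums of weights, so the extremes 0 and 1 are exact.
* Percentages are rounded to one decimal only in the report layer; raw
  fractions are kept alongside.
* Empty inputs are first-class: empty record lists give empty graphs,
  empty graphs valid CX2, absent seeds empty subgraphs, zero comparison
  pairs undefined fractions.
* Tie-breaks are deterministic everywhere: first-wins in best-match,
  highest-score-then-longest-span-then-earliest-start in grounding,
  first-appearance ordering for graph ids.
* Problem sizes in the test suite (200 random statements for the
  round-trip suite, 500 term pairs for canonical-form uniqueness, 50
  candidate sets for the argmax check, toy graphs of 7–14 nodes) were
  chosen to exercise every grammar production and graph case several
  times over while keeping the suite fast to run during development.

## Known limitations

* The BEL subset omits reactions, fusions and translocation arguments;
  statements using them fail with `bel_unknown_function`.
* The offline grounder is a whole-word dictionary: no fuzzy matching, no
  species disambiguation, no synonym expansion beyond what the lexicon
  lists.
* Sentence splitting for evidence checking is heuristic
  (punctuation-based) and can mis-split around abbreviations; the 0.9
  similarity threshold absorbs most such noise.
* Live HTTP clients (article service, grounding service, network
  exchange) are specified as contracts with offline implementations; a
  production deployment supplies its own authenticated clients.
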