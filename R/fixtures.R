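# Packaged fixtures and generators. The random statement generator
# drives the parser/serializer property suites; the two toy knowledge
# graphs (a DNA-damage-response graph and a metabolism graph sharing
# bridge nodes) stand in for networks that would normally live on an
# external exchange, so the GraphRAG demonstration runs fully offline.

.FIXTURE_GENES <- c("AKT1", "HSF1", "TP53", "MDM2", "SIRT1", "PARP1",
                    "ATM", "NAMPT", "EGFR", "BRCA1", "CHEK2", "FOXO3")
.FIXTURE_GO <- c("kinase activity", "DNA repair", "apoptotic process",
                 "catalytic activity", "autophagy")
.FIXTURE_CHEBI <- c("NAD(+)", "ATP", "resveratrol", "nicotinamide")

#' Generate a random BEL term
#'
#' Draws a random term over the supported function vocabulary, with
#' entities from a small gene/process/chemical pool, optional protein
#' modifications and nested activity/degradation/complex wrappers. Quoted
#' names (GO process names with spaces, chemical names with punctuation)
#' are generated so serializer quoting rules are exercised. Respects the
#' structural invariants checked by [validate_statement()], including the
#' maximum nesting depth of 4.
#'
#' @param max_depth Maximum remaining nesting depth.
#' @return A [bel_term()]. Uses the R random number generator; seed with
#'   `set.seed()` for reproducibility.
#' @export
random_bel_term <- function(max_depth = 3L) {
  gene_ns <- function() bel_ns("HGNC", sample(.FIXTURE_GENES, 1L))
  go_ns <- function() bel_ns("GO", sample(.FIXTURE_GO, 1L))
  chebi_ns <- function() bel_ns("CHEBI", sample(.FIXTURE_CHEBI, 1L))
  random_pmod <- function() {
    args <- list(sample(c("Ph", "Ac", "Me", "Ub"), 1L))
    if (stats::runif(1) < 0.6) {
      args <- c(args, sample(c("Ser", "Thr", "Tyr", "Lys"), 1L))
      if (stats::runif(1) < 0.7)
        args <- c(args, as.character(sample(1:999, 1L)))
    }
    bel_mod("pmod", args)
  }
  simple_protein <- function() {
    mods <- if (stats::runif(1) < 0.3) list(random_pmod()) else list()
    bel_term("p", entity = gene_ns(), mods = mods)
  }
  choice <- sample(c("p", "g", "r", "a", "bp", "act", "deg", "complex"),
                   1L, prob = c(0.30, 0.08, 0.08, 0.10, 0.12,
                                if (max_depth > 1L) 0.14 else 0,
                                if (max_depth > 1L) 0.08 else 0,
                                if (max_depth > 1L) 0.10 else 0))
  switch(choice,
    p = simple_protein(),
    g = bel_term("g", entity = gene_ns()),
    r = bel_term("r", entity = gene_ns()),
    a = bel_term("a", entity = chebi_ns()),
    bp = bel_term("bp", entity = go_ns()),
    act = {
      mods <- if (stats::runif(1) < 0.5)
        list(bel_mod("ma", list(go_ns()))) else list()
      bel_term("act", inner = list(simple_protein()), mods = mods)
    },
    deg = bel_term("deg", inner = list(simple_protein())),
    complex = bel_term("complex",
                       inner = list(simple_protein(), simple_protein())))
}

#' Generate a random BEL statement
#'
#' @param max_depth Passed to [random_bel_term()].
#' @return A [bel_statement()].
#' @export
random_bel_statement <- function(max_depth = 3L) {
  bel_statement(random_bel_term(max_depth),
                sample(bel_relations(), 1L),
                random_bel_term(max_depth))
}

.records_from_bel <- function(statements, sentences, source_id) {
  lapply(seq_along(statements), function(i)
    evidence_record(parse_bel(statements[[i]]), sentences[[i]],
                    paragraph_index = i - 1L, source_id = source_id))
}

#' Toy DNA-damage-response knowledge graph
#'
#' A small synthetic network around ATM/TP53/PARP1 signalling used by the
#' GraphRAG demonstration and tests. It shares bridge nodes (SIRT1,
#' PARP1, NAD+) with [fixture_graph_metabolism()] so that merging the two
#' graphs connects the DNA-damage and metabolism themes.
#'
#' @return A [knowledge_graph()].
#' @export
fixture_graph_dna_damage <- function() {
  stmts <- c(
    "p(HGNC:ATM) increases act(p(HGNC:TP53))",
    "act(p(HGNC:TP53)) increases p(HGNC:MDM2)",
    "p(HGNC:MDM2) decreases p(HGNC:TP53)",
    "p(HGNC:PARP1) increases bp(GO:\"DNA repair\")",
    "p(HGNC:ATM) increases p(HGNC:CHEK2)",
    "p(HGNC:SIRT1) decreases act(p(HGNC:TP53))",
    "p(HGNC:PARP1) decreases a(CHEBI:\"NAD(+)\")")
  sentences <- c(
    "ATM activates p53 after double-strand breaks.",
    "Active p53 induces MDM2 transcription.",
    "MDM2 targets p53 for degradation.",
    "PARP1 promotes DNA repair at damage sites.",
    "ATM phosphorylates and activates CHK2.",
    "SIRT1 deacetylates p53 and dampens its activity.",
    "PARP1 activation consumes cellular NAD+.")
  statements_to_graph(
    .records_from_bel(stmts, sentences, "synthetic:dna-damage"),
    name = "DNA damage response (synthetic)")
}

#' Toy metabolism knowledge graph
#'
#' A small synthetic NAD+ metabolism network; see
#' [fixture_graph_dna_damage()] for the bridging design.
#'
#' @return A [knowledge_graph()].
#' @export
fixture_graph_metabolism <- function() {
  stmts <- c(
    "p(HGNC:NAMPT) increases a(CHEBI:\"NAD(+)\")",
    "a(CHEBI:\"NAD(+)\") increases act(p(HGNC:SIRT1))",
    "act(p(HGNC:SIRT1)) increases p(HGNC:FOXO3)",
    "a(CHEBI:resveratrol) increases act(p(HGNC:SIRT1))",
    "a(CHEBI:nicotinamide) decreases act(p(HGNC:SIRT1))",
    "p(HGNC:PARP1) decreases a(CHEBI:\"NAD(+)\")")
  sentences <- c(
    "NAMPT is the rate-limiting enzyme of NAD+ salvage.",
    "NAD+ is the obligate cosubstrate for SIRT1 activity.",
    "SIRT1 activates FOXO3 target gene programs.",
    "Resveratrol stimulates SIRT1 activity.",
    "Nicotinamide inhibits SIRT1 by product feedback.",
    "PARP1 activation consumes cellular NAD+.")
  statements_to_graph(
    .records_from_bel(stmts, sentences, "synthetic:metabolism"),
    name = "NAD+ metabolism (synthetic)")
}

#' Path to the packaged fixture article XML
#'
#' A synthetic BioC-style article (passages with `section_type` infons and
#' entity annotation spans) used by offline ingestion tests and demos.
#'
#' @return File path.
#' @export
fixture_article_path <- function() {
  system.file("extdata", "fixture_article.xml", package = "beltograph")
}

#' Path to the packaged stub extraction script
#'
#' A JSON script for [stub_backend_from_file()] matching the fixture
#' article, so the end-to-end pipeline runs deterministically offline.
#'
#' @return File path.
#' @export
fixture_stub_script_path <- function() {
  system.file("extdata", "fixture_stub_script.json",
              package = "beltograph")
}
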