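# Independent oracles used by the property suites. These deliberately do
# not reuse the implementation paths they check.

# brute-force breadth-first search over an edge table, ignoring direction
# unless directed = TRUE; returns the node ids within `hops` of any seed
bfs_oracle <- function(graph, seed_ids, hops, directed = FALSE) {
  frontier <- unique(seed_ids)
  visited <- frontier
  if (length(frontier) == 0L) return(integer(0))
  for (step in seq_len(hops)) {
    nxt <- integer(0)
    for (v in frontier) {
      out_n <- graph$edges$target[graph$edges$source == v]
      in_n <- graph$edges$source[graph$edges$target == v]
      nxt <- c(nxt, out_n, if (!directed) in_n)
    }
    frontier <- setdiff(unique(nxt), visited)
    visited <- union(visited, frontier)
    if (length(frontier) == 0L) break
  }
  sort(visited)
}

# exhaustive argmax over candidates by re-scoring every one, first wins
argmax_oracle <- function(query, candidates, weights = default_weights()) {
  scores <- vapply(candidates, function(cand)
    compare_statements(query, cand, weights)$total_score, numeric(1))
  which(scores == max(scores))[1]
}

# evidence entries as order-independent keys, for graph comparison
evidence_keys <- function(ev) {
  sort(vapply(ev, function(e)
    paste(e$sentence, e$source_id, e$paragraph_index, sep = "\r"),
    character(1)))
}

# structural graph equality up to node/edge id relabeling: same canonical
# terms, and the same set of (subject term, relation, object term,
# evidence multiset) edges
expect_graph_equivalent <- function(a, b) {
  expect_setequal(a$nodes$canonical_term, b$nodes$canonical_term)
  edge_key <- function(g) {
    term_of <- function(ids) g$nodes$canonical_term[
      match(ids, g$nodes$node_id)]
    keys <- paste(term_of(g$edges$source), g$edges$relation,
                  term_of(g$edges$target))
    ev <- vapply(g$edges$evidence, function(e)
      paste(evidence_keys(e), collapse = "\n"), character(1))
    sort(paste(keys, ev, sep = "\f"))
  }
  expect_identical(edge_key(a), edge_key(b))
}

# a small pool of hand-built statements with deliberate partial overlaps,
# for comparison-scorer property tests
statement_pool <- function() {
  lapply(c(
    "p(HGNC:AKT1) increases p(HGNC:HSF1)",
    "p(HGNC:AKT1) increases p(HGNC:MDM2)",
    "p(HGNC:AKT1) decreases p(HGNC:HSF1)",
    "p(HGNC:TP53) increases p(HGNC:HSF1)",
    "p(HGNC:TP53) decreases p(HGNC:MDM2)",
    "act(p(HGNC:AKT1)) increases p(HGNC:HSF1)",
    "g(HGNC:AKT1) increases r(HGNC:HSF1)",
    "bp(GO:\"DNA repair\") association p(HGNC:PARP1)"),
    parse_bel)
}

make_paragraph <- function(text, index = 0L, section = "RESULTS",
                           source_id = "test:doc") {
  structure(list(text = text, section = section, index = as.integer(index),
                 source_id = source_id, annotations = list()),
            class = "bel_paragraph")
}

make_document <- function(texts, sections = rep("RESULTS", length(texts)),
                          source_id = "test:doc") {
  paragraphs <- lapply(seq_along(texts), function(i)
    make_paragraph(texts[[i]], index = i - 1L, section = sections[[i]],
                   source_id = source_id))
  structure(list(source_id = source_id, title = NA_character_,
                 paragraphs = paragraphs),
            class = "article_document")
}
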