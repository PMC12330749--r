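path_graph <- function() {
  # 5-node path: A - B - C - D - E
  records <- list(
    evidence_record(parse_bel("p(HGNC:ATM) increases p(HGNC:CHEK2)"),
                    "s1", 0L, "d"),
    evidence_record(parse_bel("p(HGNC:CHEK2) increases p(HGNC:TP53)"),
                    "s2", 0L, "d"),
    evidence_record(parse_bel("p(HGNC:TP53) increases p(HGNC:MDM2)"),
                    "s3", 0L, "d"),
    evidence_record(parse_bel("p(HGNC:MDM2) decreases p(HGNC:BRCA1)"),
                    "s4", 0L, "d"))
  statements_to_graph(records, name = "path graph")
}

test_that("1-hop around the center of a path graph keeps 3 nodes and 2 edges", {
  g <- path_graph()
  sub <- neighborhood(g, neighborhood_query("TP53", hops = 1))
  expect_identical(nrow(sub$nodes), 3L)
  expect_identical(nrow(sub$edges), 2L)
  expect_setequal(sub$nodes$label, c("CHEK2", "TP53", "MDM2"))
  # BFS oracle agreement
  seeds <- g$nodes$node_id[tolower(g$nodes$label) == "tp53"]
  expect_identical(sort(sub$nodes$node_id), bfs_oracle(g, seeds, 1L))
})

test_that("neighborhoods agree with the BFS oracle across seeds, hops and direction", {
  graphs <- list(path_graph(), fixture_graph_dna_damage(),
                 fixture_graph_metabolism())
  seeds_pool <- c("TP53", "SIRT1", "PARP1", "ATM", "FOXO3", "CHEK2")
  for (g in graphs) {
    for (sym in seeds_pool) {
      for (hops in 1:3) {
        for (directed in c(FALSE, TRUE)) {
          sub <- neighborhood(g, neighborhood_query(sym, hops = hops),
                              directed = directed)
          seeds <- g$nodes$node_id[
            tolower(g$nodes$label) == tolower(sym) |
              (!is.na(g$nodes$identifier) &
                 tolower(g$nodes$identifier) == tolower(sym))]
          expect_identical(sort(sub$nodes$node_id),
                           bfs_oracle(g, seeds, hops, directed))
          # induced subgraph: both endpoints of every edge included
          expect_true(all(sub$edges$source %in% sub$nodes$node_id))
          expect_true(all(sub$edges$target %in% sub$nodes$node_id))
        }
      }
    }
  }
})

test_that("absent seeds give the empty subgraph and large hops the full component", {
  g <- path_graph()
  none <- neighborhood(g, neighborhood_query("NOTAGENE"))
  expect_identical(nrow(none$nodes), 0L)
  expect_identical(nrow(none$edges), 0L)
  # hops >= diameter reaches the whole connected component
  all_of_it <- neighborhood(g, neighborhood_query("TP53", hops = 10))
  expect_identical(sort(all_of_it$nodes$node_id), sort(g$nodes$node_id))
  expect_identical(nrow(all_of_it$edges), nrow(g$edges))
})

test_that("hop-k subgraphs are contained in hop-(k+1) subgraphs", {
  g <- fixture_graph_dna_damage()
  prev <- integer(0)
  for (hops in 1:4) {
    sub <- neighborhood(g, neighborhood_query("MDM2", hops = hops))
    expect_true(all(prev %in% sub$nodes$node_id))
    prev <- sub$nodes$node_id
  }
})

test_that("merging graphs unions nodes and edges with provenance, matching a set oracle", {
  a <- fixture_graph_dna_damage()
  b <- fixture_graph_metabolism()
  m <- merge_graphs(list(a, b))
  expect_setequal(m$nodes$canonical_term,
                  union(a$nodes$canonical_term, b$nodes$canonical_term))
  triple_of <- function(g) {
    term <- function(ids) g$nodes$canonical_term[
      match(ids, g$nodes$node_id)]
    paste(term(g$edges$source), g$edges$relation, term(g$edges$target))
  }
  expect_setequal(triple_of(m), union(triple_of(a), triple_of(b)))
  # the shared PARP1 -| NAD+ edge carries provenance from both inputs
  shared <- which(triple_of(m) ==
                    'p(HGNC:PARP1) decreases a(CHEBI:"NAD(+)")')
  expect_setequal(m$edges$source_network[[shared]], c(a$name, b$name))
})

test_that("merge is idempotent on one graph and additive on disjoint graphs", {
  a <- fixture_graph_dna_damage()
  expect_graph_equivalent(merge_graphs(list(a, a)), a)
  left <- statements_to_graph(list(
    evidence_record(parse_bel("p(HGNC:ATM) increases p(HGNC:CHEK2)"),
                    "s", 0L, "d1")), name = "left")
  right <- statements_to_graph(list(
    evidence_record(parse_bel("p(HGNC:NAMPT) increases a(CHEBI:\"NAD(+)\")"),
                    "s", 0L, "d2")), name = "right")
  m <- merge_graphs(list(left, right))
  expect_identical(nrow(m$nodes), nrow(left$nodes) + nrow(right$nodes))
  expect_identical(nrow(m$edges), nrow(left$edges) + nrow(right$edges))
})

test_that("merge is commutative and associative up to id relabeling", {
  a <- fixture_graph_dna_damage()
  b <- fixture_graph_metabolism()
  c3 <- path_graph()
  expect_graph_equivalent(merge_graphs(list(a, b)),
                          merge_graphs(list(b, a)))
  expect_graph_equivalent(
    merge_graphs(list(merge_graphs(list(a, b)), c3)),
    merge_graphs(list(a, merge_graphs(list(b, c3)))))
})

test_that("prompt contexts embed the subgraph as CX2 that parses back", {
  g <- fixture_graph_metabolism()
  q <- neighborhood_query("SIRT1", hops = 1)
  sub <- neighborhood(g, q)
  prompt <- build_context(sub, q, "What regulates SIRT1?")
  expect_match(prompt, "ONLY the knowledge graph", fixed = TRUE)
  cx2_text <- sub("^.*Knowledge graph \\(CX2 JSON\\):\n", "",
                  strsplit(prompt, "\n\nQuestion:")[[1]][1])
  back <- cx2_to_graph(jsonlite::fromJSON(cx2_text,
                                          simplifyVector = FALSE))
  expect_identical(back$nodes, sub$nodes)
  expect_identical(back$edges, sub$edges)
  # the internal-knowledge toggle flips exactly one instruction block
  q2 <- neighborhood_query("SIRT1", hops = 1,
                           use_internal_knowledge = TRUE)
  prompt2 <- build_context(sub, q2, "What regulates SIRT1?")
  expect_match(prompt2, "your own internal", fixed = TRUE)
  tail_of <- function(x) sub("^[^\n]*\n", "", x)
  expect_identical(tail_of(prompt), tail_of(prompt2))
  # empty subgraph prompts say so
  empty_prompt <- build_context(statements_to_graph(list()), q, "Q?")
  expect_match(empty_prompt, "empty", fixed = TRUE)
})

test_that("the demonstration runs seven variations over two graphs and their merge", {
  a <- fixture_graph_dna_damage()
  b <- fixture_graph_metabolism()
  tr <- run_demo(list(a, b), "How does metabolism affect DNA damage response?",
                 genes = c("SIRT1", "PARP1"))
  expect_length(tr, 7)
  labels <- vapply(tr, `[[`, character(1), "label")
  expect_identical(sum(grepl("merged", labels)), 2L)
  expect_identical(sum(labels == "no knowledge graph"), 1L)
  # the merged-case prompt embeds the CX2 of the merged neighborhood
  q <- neighborhood_query(c("SIRT1", "PARP1"), hops = 1,
                          use_internal_knowledge = FALSE)
  merged_sub <- neighborhood(merge_graphs(list(a, b)), q)
  expect_match(tr[[5]]$prompt, cx2_to_json(graph_to_cx2(merged_sub)),
               fixed = TRUE)
  expect_error(run_demo(list(a), "q", genes = "SIRT1"),
               class = "bel_precondition_error")
})
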