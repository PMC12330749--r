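# GraphRAG-style retrieval: pull the k-hop neighborhood of query genes
# out of a knowledge graph and embed it, as CX2 JSON, into an LLM prompt
# context. Traversal is undirected by default (a gene's neighborhood
# includes both its regulators and its targets); directed mode follows
# edge direction only.

#' Construct a neighborhood query
#'
#' @param gene_symbols Non-empty character vector of query gene symbols.
#' @param hops Number of hops outward from the seed nodes (>= 1).
#' @param use_internal_knowledge Whether the downstream prompt invites the
#'   model to combine the graph with its own knowledge.
#' @return Object of class `neighborhood_query`.
#' @export
neighborhood_query <- function(gene_symbols, hops = 1L,
                               use_internal_knowledge = FALSE) {
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) == 0L)
    .bel_error("gene list must be non-empty", "bel_precondition_error")
  hops <- as.integer(hops)
  if (is.na(hops) || hops < 1L)
    .bel_error("hops must be a positive integer", "bel_precondition_error")
  structure(list(gene_symbols = gene_symbols, hops = hops,
                 use_internal_knowledge = isTRUE(use_internal_knowledge)),
            class = "neighborhood_query")
}

# seed nodes: label OR identifier equality, case-insensitive, exact token
.seed_node_ids <- function(graph, gene_symbols) {
  syms <- tolower(gene_symbols)
  hit <- tolower(graph$nodes$label) %in% syms |
    (!is.na(graph$nodes$identifier) &
       tolower(graph$nodes$identifier) %in% syms)
  graph$nodes$node_id[hit]
}

.subgraph_by_node_ids <- function(graph, node_ids) {
  nodes <- graph$nodes[graph$nodes$node_id %in% node_ids, , drop = FALSE]
  keep_edge <- graph$edges$source %in% node_ids &
    graph$edges$target %in% node_ids
  edges <- graph$edges[keep_edge, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  knowledge_graph(nodes, edges, name = graph$name,
                  attributes = graph$attributes)
}

#' Retrieve the k-hop neighborhood of query genes
#'
#' Seed nodes are matched by node label or entity identifier
#' (case-insensitive, exact token). The result is the subgraph induced by
#' the seeds plus every node within `hops` steps of a seed, including all
#' edges among the included nodes. Seeds absent from the graph contribute
#' nothing; the empty subgraph is a valid result.
#'
#' @param graph A [knowledge_graph()].
#' @param query A [neighborhood_query()], or a character vector of gene
#'   symbols (1-hop, no internal knowledge).
#' @param directed Follow edge direction during traversal instead of the
#'   default undirected expansion.
#' @return The induced-subgraph [knowledge_graph()] (original node and
#'   edge ids preserved).
#' @export
neighborhood <- function(graph, query, directed = FALSE) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (is.character(query)) query <- neighborhood_query(query)
  seeds <- .seed_node_ids(graph, query$gene_symbols)
  if (length(seeds) == 0L) return(.subgraph_by_node_ids(graph, integer(0)))
  if (nrow(graph$edges) == 0L)
    return(.subgraph_by_node_ids(graph, seeds))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$source),
               to = as.character(graph$edges$target),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph$nodes$node_id),
                          stringsAsFactors = FALSE))
  reached <- igraph::ego(ig, order = query$hops,
                         nodes = as.character(seeds),
                         mode = if (directed) "out" else "all")
  ids <- unique(as.integer(unlist(lapply(reached, names))))
  .subgraph_by_node_ids(graph, ids)
}

#' Merge knowledge graphs with node and edge deduplication
#'
#' Nodes are deduplicated by canonical BEL term and edges by their
#' (subject, relation, object) triple; evidence lists of merged edges are
#' concatenated. A provenance attribute (`source_network`) records, per
#' node and edge, which input network(s) contributed it. Node and edge ids
#' are reassigned in first-appearance order.
#'
#' @param graphs Non-empty list of [knowledge_graph()]s.
#' @param name Name of the merged network.
#' @return A [knowledge_graph()] whose node and edge tables carry a
#'   `source_network` list-column.
#' @export
merge_graphs <- function(graphs, name = "merged network") {
  if (length(graphs) == 0L)
    .bel_error("at least one graph is required", "bel_precondition_error")
  for (g in graphs) stopifnot(inherits(g, "knowledge_graph"))
  node_rows <- list()
  node_index <- new.env(parent = emptyenv())
  edge_rows <- list()
  edge_index <- new.env(parent = emptyenv())
  sources <- character(0)

  for (g in graphs) {
    sources <- union(sources, as.character(g$attributes$sources %||%
                                             character(0)))
    id_map <- integer(nrow(g$nodes))
    names(id_map) <- as.character(g$nodes$node_id)
    for (i in seq_len(nrow(g$nodes))) {
      key <- g$nodes$canonical_term[i]
      if (is.null(node_index[[key]])) {
        new_id <- length(node_rows)
        node_rows[[new_id + 1L]] <- list(
          node_id = new_id, canonical_term = key,
          label = g$nodes$label[i], namespace = g$nodes$namespace[i],
          identifier = g$nodes$identifier[i],
          source_network = g$name)
        node_index[[key]] <- new_id
      } else {
        new_id <- node_index[[key]]
        prov <- node_rows[[new_id + 1L]]$source_network
        node_rows[[new_id + 1L]]$source_network <- union(prov, g$name)
      }
      id_map[[as.character(g$nodes$node_id[i])]] <- new_id
    }
    for (i in seq_len(nrow(g$edges))) {
      src <- id_map[[as.character(g$edges$source[i])]]
      tgt <- id_map[[as.character(g$edges$target[i])]]
      key <- paste(src, g$edges$relation[i], tgt, g$edges$bel[i],
                   sep = "\r")
      ev <- g$edges$evidence[[i]]
      if (is.null(edge_index[[key]])) {
        new_id <- length(edge_rows)
        edge_rows[[new_id + 1L]] <- list(
          edge_id = new_id, source = src, target = tgt,
          relation = g$edges$relation[i], bel = g$edges$bel[i],
          evidence = ev, source_network = g$name)
        edge_index[[key]] <- new_id
      } else {
        new_id <- edge_index[[key]]
        row <- edge_rows[[new_id + 1L]]
        merged_ev <- c(row$evidence, ev)
        merged_ev <- merged_ev[!duplicated(vapply(merged_ev, function(e)
          paste(e$sentence, e$source_id, e$paragraph_index, sep = "\r"),
          character(1)))]
        row$evidence <- merged_ev
        row$source_network <- union(row$source_network, g$name)
        edge_rows[[new_id + 1L]] <- row
      }
    }
  }

  nodes <- data.frame(
    node_id = vapply(node_rows, `[[`, integer(1), "node_id"),
    canonical_term = vapply(node_rows, `[[`, character(1),
                            "canonical_term"),
    label = vapply(node_rows, `[[`, character(1), "label"),
    namespace = vapply(node_rows, `[[`, character(1), "namespace"),
    identifier = vapply(node_rows, `[[`, character(1), "identifier"),
    stringsAsFactors = FALSE)
  nodes$source_network <- lapply(node_rows, `[[`, "source_network")
  edges <- data.frame(
    edge_id = vapply(edge_rows, `[[`, integer(1), "edge_id"),
    source = vapply(edge_rows, `[[`, integer(1), "source"),
    target = vapply(edge_rows, `[[`, integer(1), "target"),
    relation = vapply(edge_rows, `[[`, character(1), "relation"),
    bel = vapply(edge_rows, `[[`, character(1), "bel"),
    stringsAsFactors = FALSE)
  edges$evidence <- lapply(edge_rows, `[[`, "evidence")
  edges$source_network <- lapply(edge_rows, `[[`, "source_network")
  if (length(node_rows) == 0L)
    return(knowledge_graph(name = name,
                           attributes = list(sources = sources,
                                             generated_by = "beltograph")))
  knowledge_graph(nodes, edges, name = name,
                  attributes = list(sources = sources,
                                    generated_by = "beltograph"))
}

#' Build an LLM prompt context around a retrieved subgraph
#'
#' Embeds the subgraph as CX2 JSON together with the user question and an
#' instruction block selected by `use_internal_knowledge`: either answer
#' strictly from the graph, or combine the graph with the model's own
#' knowledge. The text is deterministic given its inputs.
#'
#' @param subgraph A [knowledge_graph()] (may be empty).
#' @param query A [neighborhood_query()].
#' @param question The user question text.
#' @return A single prompt string.
#' @export
build_context <- function(subgraph, query, question) {
  stopifnot(inherits(subgraph, "knowledge_graph"))
  instruction <- if (isTRUE(query$use_internal_knowledge)) {
    paste("Combine the knowledge graph below with your own internal",
          "knowledge to answer the question.")
  } else {
    paste("Answer the question using ONLY the knowledge graph below;",
          "do not use any other knowledge.")
  }
  graph_block <- if (nrow(subgraph$nodes) == 0L) {
    "The knowledge graph is empty: no statements were retrieved."
  } else {
    paste0("Knowledge graph (CX2 JSON):\n",
           cx2_to_json(graph_to_cx2(subgraph)))
  }
  paste(instruction, graph_block, paste0("Question: ", question),
        sep = "\n\n")
}

#' Run the seven-variation GraphRAG demonstration
#'
#' Poses one question under seven retrieval conditions: each of two
#' knowledge graphs and their merge, each with and without the model's
#' internal knowledge (6 variations), plus a no-graph baseline. Backend
#' failures are recorded per variation instead of aborting the run.
#'
#' @param graphs List of exactly two [knowledge_graph()]s.
#' @param question The question text.
#' @param backend An LLM backend with an `answer(prompt)` or
#'   `judge(prompt)`-style completion function; any backend exposing
#'   `answer` is used, otherwise the prompt is returned with an `NA`
#'   response (prompt-only transcript).
#' @param genes Seed gene symbols for the neighborhood retrieval.
#' @param hops Neighborhood radius.
#' @return List of 7 transcript entries `list(label, prompt, response,
#'   error)`.
#' @export
run_demo <- function(graphs, question, backend = NULL,
                     genes, hops = 1L) {
  if (length(graphs) != 2L)
    .bel_error("the demonstration takes exactly two graphs",
               "bel_precondition_error")
  merged <- merge_graphs(graphs)
  cases <- list(
    list(label = paste0(graphs[[1]]$name, " / graph only"),
         graph = graphs[[1]], internal = FALSE),
    list(label = paste0(graphs[[1]]$name, " / graph + internal"),
         graph = graphs[[1]], internal = TRUE),
    list(label = paste0(graphs[[2]]$name, " / graph only"),
         graph = graphs[[2]], internal = FALSE),
    list(label = paste0(graphs[[2]]$name, " / graph + internal"),
         graph = graphs[[2]], internal = TRUE),
    list(label = "merged / graph only", graph = merged, internal = FALSE),
    list(label = "merged / graph + internal", graph = merged,
         internal = TRUE),
    list(label = "no knowledge graph", graph = NULL, internal = TRUE))
  transcript <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    prompt <- if (is.null(case$graph)) {
      paste("Answer the question from your own knowledge.",
            paste0("Question: ", question), sep = "\n\n")
    } else {
      q <- neighborhood_query(genes, hops = hops,
                              use_internal_knowledge = case$internal)
      build_context(neighborhood(case$graph, q), q, question)
    }
    response <- NA_character_
    err <- NA_character_
    if (!is.null(backend) && !is.null(backend$answer)) {
      out <- tryCatch(backend$answer(prompt), error = identity)
      if (inherits(out, "error")) err <- conditionMessage(out)
      else response <- out
    }
    transcript[[i]] <- list(label = case$label, prompt = prompt,
                            response = response, error = err)
  }
  transcript
}
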