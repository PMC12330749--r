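# Knowledge-graph construction: evidence records -> deduplicated
# property graph. Node identity is the canonical BEL term string, so a
# protein and its activity (p(X) vs act(p(X))) are distinct nodes; edges
# deduplicate on the (subject, relation, object) triple with evidence
# lists merged, or one-edge-per-evidence when collapse_edges = FALSE.

#' Construct a knowledge graph container
#'
#' @param nodes Data frame with columns `node_id`, `canonical_term`,
#'   `label`, `namespace`, `identifier`.
#' @param edges Data frame with columns `edge_id`, `source`, `target`,
#'   `relation`, `bel` and a list-column `evidence` (each element a list
#'   of `list(sentence, source_id, paragraph_index)`).
#' @param name Network name.
#' @param attributes Named list of network attributes.
#' @return Object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes = NULL, edges = NULL,
                            name = "knowledge graph",
                            attributes = list()) {
  if (is.null(nodes))
    nodes <- data.frame(node_id = integer(0), canonical_term = character(0),
                        label = character(0), namespace = character(0),
                        identifier = character(0), stringsAsFactors = FALSE)
  if (is.null(edges)) {
    edges <- data.frame(edge_id = integer(0), source = integer(0),
                        target = integer(0), relation = character(0),
                        bel = character(0), stringsAsFactors = FALSE)
    edges$evidence <- list()
  }
  if (anyDuplicated(nodes$node_id) || anyDuplicated(edges$edge_id))
    .bel_error("node/edge ids must be unique", "bel_value_error")
  if (anyDuplicated(nodes$canonical_term))
    .bel_error("canonical_term must be unique across nodes",
               "bel_value_error")
  if (nrow(edges) > 0L &&
      !all(c(edges$source, edges$target) %in% nodes$node_id))
    .bel_error("edge endpoints must reference existing nodes",
               "bel_value_error")
  structure(list(name = name, nodes = nodes, edges = edges,
                 attributes = attributes),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> '", x$name, "': ", nrow(x$nodes), " node(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

# display label for a term: identifier of its primary entity, falling
# back to the canonical string for entity-free terms
.term_display <- function(term) {
  e <- .primary_entity(term)
  if (!is.null(e)) e$id else .serialize_term(term)
}

#' Build a deduplicated knowledge graph from evidence records
#'
#' Every distinct canonical subject/object term becomes one node (numeric
#' ids assigned in first-appearance order starting at 0). With
#' `collapse_edges = TRUE` (default) one edge is created per distinct
#' (subject, relation, object) triple and the supporting evidence entries
#' are merged onto it; with `FALSE` each record contributes its own edge.
#'
#' @param records List of [evidence_record()]s with parse-valid
#'   statements.
#' @param name Network name.
#' @param collapse_edges Merge duplicate triples into one edge.
#' @return A [knowledge_graph()].
#' @export
statements_to_graph <- function(records, name = "knowledge graph",
                                collapse_edges = TRUE) {
  node_terms <- character(0)
  node_label <- character(0)
  node_ns <- character(0)
  node_id_field <- character(0)
  node_index <- new.env(parent = emptyenv())

  intern_node <- function(term) {
    key <- .serialize_term(term)
    if (!is.null(node_index[[key]])) return(node_index[[key]])
    id <- length(node_terms)
    node_terms[[id + 1L]] <<- key
    node_label[[id + 1L]] <<- .term_display(term)
    e <- .primary_entity(term)
    node_ns[[id + 1L]] <<- if (is.null(e)) NA_character_ else e$namespace
    node_id_field[[id + 1L]] <<- if (is.null(e)) NA_character_ else e$id
    node_index[[key]] <- id
    id
  }

  edge_keys <- character(0)
  edge_src <- integer(0)
  edge_tgt <- integer(0)
  edge_rel <- character(0)
  edge_bel <- character(0)
  edge_evidence <- list()
  edge_index <- new.env(parent = emptyenv())
  sources <- character(0)

  for (r in records) {
    stopifnot(inherits(r, "evidence_record"))
    s <- intern_node(r$statement$subject)
    o <- intern_node(r$statement$object)
    bel <- serialize_bel(r$statement)
    ev <- list(sentence = r$evidence_sentence, source_id = r$source_id,
               paragraph_index = r$paragraph_index)
    if (!is.na(r$source_id)) sources <- union(sources, r$source_id)
    key <- if (collapse_edges) bel else
      paste0(bel, "#", length(edge_keys))
    if (!is.null(edge_index[[key]])) {
      i <- edge_index[[key]] + 1L
      edge_evidence[[i]] <- c(edge_evidence[[i]], list(ev))
    } else {
      i <- length(edge_keys) + 1L
      edge_keys[[i]] <- key
      edge_src[[i]] <- s
      edge_tgt[[i]] <- o
      edge_rel[[i]] <- r$statement$relation
      edge_bel[[i]] <- bel
      edge_evidence[[i]] <- list(ev)
      edge_index[[key]] <- i - 1L
    }
  }

  nodes <- data.frame(node_id = seq_along(node_terms) - 1L,
                      canonical_term = as.character(node_terms),
                      label = as.character(node_label),
                      namespace = as.character(node_ns),
                      identifier = as.character(node_id_field),
                      stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = seq_along(edge_keys) - 1L,
                      source = as.integer(edge_src),
                      target = as.integer(edge_tgt),
                      relation = as.character(edge_rel),
                      bel = as.character(edge_bel),
                      stringsAsFactors = FALSE)
  edges$evidence <- edge_evidence
  knowledge_graph(nodes, edges, name = name,
                  attributes = list(sources = sources,
                                    generated_by = "beltograph"))
}

#' Upload a knowledge graph through an NDEx-style client
#'
#' Pure pass-through: serializes the graph with [graph_to_cx2()] and hands
#' it to the client's `save_network`, returning the service-assigned
#' network identifier verbatim.
#'
#' @param graph A [knowledge_graph()].
#' @param client A client contract, e.g. [mock_ndex_client()] or a live
#'   NDEx client wrapper.
#' @return The network identifier returned by the service.
#' @export
upload_network <- function(graph, client) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (is.null(client$save_network))
    .bel_error("client does not implement save_network",
               "bel_precondition_error")
  client$save_network(graph_to_cx2(graph))
}
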