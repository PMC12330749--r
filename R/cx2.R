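# CX2 (Cytoscape Exchange v2) import/export. CX2 is an aspect-oriented
# JSON array; the writer emits CXVersion, attributeDeclarations,
# networkAttributes, nodes, edges and status aspects with declared
# attribute types and a stable key order, so output is byte-stable.
#
# Edge evidence entries (sentence, source article, paragraph index) are
# stored as three parallel list attributes on each edge and zipped back
# together on read, keeping the read/write pair an exact inverse on this
# package's own output while remaining a tolerant reader for foreign CX2
# (missing BEL attributes degrade to label-only nodes).

.cx2_attribute_declarations <- function() {
  list(
    networkAttributes = list(
      name = list(d = "string"),
      sources = list(d = "list_of_string"),
      generated_by = list(d = "string")),
    nodes = list(
      name = list(d = "string"),
      bel = list(d = "string"),
      namespace = list(d = "string"),
      identifier = list(d = "string")),
    edges = list(
      interaction = list(d = "string"),
      bel = list(d = "string"),
      evidence = list(d = "list_of_string"),
      source = list(d = "list_of_string"),
      paragraph = list(d = "list_of_long"))
  )
}

#' Convert a knowledge graph to a CX2 document
#'
#' @param graph A [knowledge_graph()].
#' @return The CX2 document as a list of aspect objects, ready for
#'   [write_cx2()] / `jsonlite::toJSON`.
#' @export
graph_to_cx2 <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  nodes_aspect <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    row <- graph$nodes[i, ]
    v <- list(name = row$label, bel = row$canonical_term)
    if (!is.na(row$namespace)) v$namespace <- row$namespace
    if (!is.na(row$identifier)) v$identifier <- row$identifier
    list(id = row$node_id, v = v)
  })
  edges_aspect <- lapply(seq_len(nrow(graph$edges)), function(i) {
    row <- graph$edges[i, ]
    ev <- graph$edges$evidence[[i]]
    v <- list(
      interaction = row$relation,
      bel = row$bel,
      evidence = I(vapply(ev, function(e) as.character(e$sentence),
                          character(1))),
      source = I(vapply(ev, function(e) as.character(e$source_id),
                        character(1))),
      paragraph = I(vapply(ev, function(e) as.integer(e$paragraph_index),
                           integer(1))))
    list(id = row$edge_id, s = row$source, t = row$target, v = v)
  })
  net_attrs <- list(name = graph$name)
  net_attrs$sources <- I(as.character(graph$attributes$sources %||%
                                        character(0)))
  net_attrs$generated_by <- graph$attributes$generated_by %||% "beltograph"
  list(
    list(CXVersion = "2.0", hasFragments = FALSE),
    list(attributeDeclarations = list(.cx2_attribute_declarations())),
    list(networkAttributes = list(net_attrs)),
    list(nodes = nodes_aspect),
    list(edges = edges_aspect),
    list(status = list(list(success = TRUE)))
  )
}

#' Write a knowledge graph as CX2 JSON
#'
#' @param graph A [knowledge_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cx2 <- function(graph, path) {
  writeLines(cx2_to_json(graph_to_cx2(graph)), path, useBytes = TRUE)
  invisible(path)
}

#' Serialize a CX2 document list to its JSON text
#'
#' @param doc A CX2 document list, as produced by [graph_to_cx2()].
#' @return A single JSON string (compact, stable key order).
#' @export
cx2_to_json <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

.find_aspect <- function(doc, name) {
  for (aspect in doc) {
    if (is.list(aspect) && name %in% names(aspect))
      return(aspect[[name]])
  }
  NULL
}

.chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

#' Read a CX2 document into a knowledge graph
#'
#' Exact inverse of [graph_to_cx2()] on this package's own output. For
#' foreign CX2 the reader is tolerant: nodes missing the `bel` attribute
#' fall back to their `name` as the canonical term, and missing evidence
#' attributes yield empty evidence lists.
#'
#' @param doc A CX2 document list (parsed JSON), or see [read_cx2()].
#' @return A [knowledge_graph()].
#' @export
cx2_to_graph <- function(doc) {
  if (!is.list(doc))
    .bel_error("CX2 document must be a list of aspects", "bel_parse_error")
  nodes_aspect <- .find_aspect(doc, "nodes")
  edges_aspect <- .find_aspect(doc, "edges")
  if (is.null(nodes_aspect))
    .bel_error("CX2 document has no 'nodes' aspect", "bel_parse_error")
  net_aspect <- .find_aspect(doc, "networkAttributes")

  parse_entry <- function(entry, aspect) {
    if (!is.list(entry) || is.null(entry$id))
      .bel_error(sprintf("malformed entry in '%s' aspect", aspect),
                 "bel_parse_error")
    entry
  }

  n <- length(nodes_aspect)
  nodes <- data.frame(node_id = integer(n), canonical_term = character(n),
                      label = character(n), namespace = character(n),
                      identifier = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    entry <- parse_entry(nodes_aspect[[i]], "nodes")
    v <- entry$v %||% list()
    label <- .chr_or_na(v$name)
    nodes$node_id[i] <- as.integer(entry$id)
    nodes$canonical_term[i] <- if (!is.null(v$bel)) as.character(v$bel)
                               else label
    nodes$label[i] <- label
    nodes$namespace[i] <- .chr_or_na(v$namespace)
    nodes$identifier[i] <- .chr_or_na(v$identifier)
  }

  m <- length(edges_aspect)
  edges <- data.frame(edge_id = integer(m), source = integer(m),
                      target = integer(m), relation = character(m),
                      bel = character(m), stringsAsFactors = FALSE)
  evidence <- vector("list", m)
  for (i in seq_len(m)) {
    entry <- parse_entry(edges_aspect[[i]], "edges")
    if (is.null(entry$s) || is.null(entry$t))
      .bel_error("malformed entry in 'edges' aspect", "bel_parse_error")
    v <- entry$v %||% list()
    edges$edge_id[i] <- as.integer(entry$id)
    edges$source[i] <- as.integer(entry$s)
    edges$target[i] <- as.integer(entry$t)
    edges$relation[i] <- .chr_or_na(v$interaction)
    edges$bel[i] <- .chr_or_na(v$bel)
    sentences <- vapply(v$evidence %||% list(), as.character, character(1))
    srcs <- vapply(v$source %||% list(), as.character, character(1))
    paras <- vapply(v$paragraph %||% list(), as.integer, integer(1))
    evidence[[i]] <- lapply(seq_along(sentences), function(k)
      list(sentence = sentences[[k]],
           source_id = if (k <= length(srcs)) srcs[[k]] else NA_character_,
           paragraph_index = if (k <= length(paras)) paras[[k]]
                             else NA_integer_))
  }
  edges$evidence <- evidence

  name <- "knowledge graph"
  attributes <- list(sources = character(0), generated_by = "beltograph")
  if (!is.null(net_aspect) && length(net_aspect) >= 1L) {
    na <- net_aspect[[1]]
    if (!is.null(na$name)) name <- as.character(na$name)
    if (!is.null(na$sources))
      attributes$sources <- vapply(na$sources, as.character, character(1))
    if (!is.null(na$generated_by))
      attributes$generated_by <- as.character(na$generated_by)
  }
  knowledge_graph(nodes, edges, name = name, attributes = attributes)
}

#' Read a CX2 JSON file into a knowledge graph
#'
#' @param path Path to a CX2 JSON file.
#' @return A [knowledge_graph()].
#' @export
read_cx2 <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    .bel_error(sprintf("cannot parse CX2 JSON: %s",
                                       conditionMessage(e)),
                               "bel_parse_error"))
  cx2_to_graph(doc)
}
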