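#' @title BEL domain model
#' @description
#' S3 types for the causal BEL subset handled by the package: namespaced
#' entities, term modifications, functionally composed terms, and
#' subject-predicate-object statements.
#' @name bel-model
#' @keywords internal
NULL

# closed vocabularies; extensible through options(beltograph.*)
.BEL_FUNCTIONS <- c("p", "g", "r", "a", "complex", "bp", "path",
                    "act", "deg", "tloc")
.BEL_RELATIONS <- c("increases", "decreases", "directlyIncreases",
                    "directlyDecreases", "association", "regulates")
.BEL_MOD_KINDS <- c("pmod", "ma", "frag", "loc")
.BEL_NAMESPACES <- c("HGNC", "GO", "CHEBI", "MESH", "UNIPROT", "NCBIGENE",
                     "FPLX", "DOID", "HP", "EFO", "INTERPRO", "PUBCHEM")

#' Vocabularies of the supported BEL subset
#'
#' The subset covers plain and composed entity functions plus the common
#' causal/correlative relations. Each vocabulary can be extended via the
#' corresponding option (`beltograph.functions`, `beltograph.relations`,
#' `beltograph.namespaces`).
#'
#' @return Character vector of allowed tokens.
#' @export
bel_functions <- function() getOption("beltograph.functions", .BEL_FUNCTIONS)

#' @rdname bel_functions
#' @export
bel_relations <- function() getOption("beltograph.relations", .BEL_RELATIONS)

#' @rdname bel_functions
#' @export
bel_namespaces <- function() getOption("beltograph.namespaces", .BEL_NAMESPACES)

#' @rdname bel_functions
#' @export
bel_modification_kinds <- function() .BEL_MOD_KINDS

.bel_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "bel_error", "error"), ...))
}

#' Construct a namespace-qualified identifier
#'
#' @param namespace Short vocabulary code, e.g. `"HGNC"`. Uppercased on
#'   construction; must be in [bel_namespaces()].
#' @param id Identifier or name token; quoted on serialization when it
#'   contains characters outside `[A-Za-z0-9_]`.
#' @return Object of class `bel_ns`.
#' @export
bel_ns <- function(namespace, id) {
  namespace <- toupper(as.character(namespace))
  id <- as.character(id)
  if (!nzchar(namespace) || !nzchar(id))
    .bel_error("namespace and identifier must be non-empty", "bel_value_error")
  if (!namespace %in% bel_namespaces())
    .bel_error(sprintf("unknown namespace '%s'", namespace),
               "bel_unknown_namespace")
  structure(list(namespace = namespace, id = id), class = "bel_ns")
}

#' Construct a term modification
#'
#' Modifications are the `pmod`/`ma`/`frag`/`loc` sub-expressions that
#' decorate a term (e.g. `pmod(Ph, Ser, 326)` for phosphorylation at a
#' serine residue).
#'
#' @param kind One of [bel_modification_kinds()].
#' @param args List of character tokens and/or [bel_ns()] objects, in
#'   grammar order.
#' @return Object of class `bel_mod`.
#' @export
bel_mod <- function(kind, args = list()) {
  kind <- as.character(kind)
  if (!kind %in% .BEL_MOD_KINDS)
    .bel_error(sprintf("unknown modification kind '%s'", kind),
               "bel_unknown_function")
  if (!is.list(args)) args <- as.list(args)
  if (kind == "pmod" && (length(args) < 1L || length(args) > 3L))
    .bel_error("pmod takes 1 to 3 arguments", "bel_value_error")
  structure(list(kind = kind, args = args), class = "bel_mod")
}

#' Construct a BEL term
#'
#' A term is a BEL function applied to an optional namespaced entity, inner
#' terms and modifications, e.g. `p(HGNC:AKT1)` or
#' `act(p(HGNC:AKT1), ma(GO:"kinase activity"))`.
#'
#' @param fn Function token, one of [bel_functions()].
#' @param entity Optional [bel_ns()].
#' @param inner List of inner `bel_term` objects.
#' @param mods List of [bel_mod()] objects.
#' @return Object of class `bel_term`.
#' @export
bel_term <- function(fn, entity = NULL, inner = list(), mods = list()) {
  fn <- as.character(fn)
  if (!fn %in% bel_functions())
    .bel_error(sprintf("unknown BEL function '%s'", fn),
               "bel_unknown_function")
  structure(list(fn = fn, entity = entity, inner = inner, mods = mods),
            class = "bel_term")
}

#' Construct a BEL statement
#'
#' @param subject,object [bel_term()] objects.
#' @param relation Relation token, one of [bel_relations()] (case-sensitive).
#' @return Object of class `bel_statement`.
#' @export
bel_statement <- function(subject, relation, object) {
  if (!inherits(subject, "bel_term") || !inherits(object, "bel_term"))
    .bel_error("subject and object must be bel_term objects",
               "bel_value_error")
  if (!relation %in% bel_relations())
    .bel_error(sprintf("unknown relation '%s'", relation),
               "bel_unknown_relation")
  structure(list(subject = subject, relation = as.character(relation),
                 object = object), class = "bel_statement")
}

#' Structural equality of BEL objects
#'
#' Recursive field-by-field comparison of terms, statements, namespace ids
#' and modifications. Independent of the canonical serializer, so the two
#' can be cross-checked against each other.
#'
#' @param a,b Objects of the same BEL S3 class.
#' @return `TRUE` or `FALSE`.
#' @export
bel_equal <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (inherits(a, "bel_ns"))
    return(a$namespace == b$namespace && a$id == b$id)
  if (inherits(a, "bel_mod")) {
    if (a$kind != b$kind || length(a$args) != length(b$args)) return(FALSE)
    for (i in seq_along(a$args)) {
      x <- a$args[[i]]; y <- b$args[[i]]
      if (inherits(x, "bel_ns") || inherits(y, "bel_ns")) {
        if (!bel_equal(x, y)) return(FALSE)
      } else if (!identical(as.character(x), as.character(y))) return(FALSE)
    }
    return(TRUE)
  }
  if (inherits(a, "bel_term")) {
    if (a$fn != b$fn) return(FALSE)
    if (is.null(a$entity) != is.null(b$entity)) return(FALSE)
    if (!is.null(a$entity) && !bel_equal(a$entity, b$entity)) return(FALSE)
    if (length(a$inner) != length(b$inner) ||
        length(a$mods) != length(b$mods)) return(FALSE)
    for (i in seq_along(a$inner))
      if (!bel_equal(a$inner[[i]], b$inner[[i]])) return(FALSE)
    for (i in seq_along(a$mods))
      if (!bel_equal(a$mods[[i]], b$mods[[i]])) return(FALSE)
    return(TRUE)
  }
  if (inherits(a, "bel_statement"))
    return(a$relation == b$relation &&
             bel_equal(a$subject, b$subject) &&
             bel_equal(a$object, b$object))
  identical(a, b)
}

# depth of a term tree; a leaf term has depth 1
.term_depth <- function(term) {
  if (length(term$inner) == 0L) return(1L)
  1L + max(vapply(term$inner, .term_depth, integer(1)))
}

# first namespaced entity encountered in a depth-first walk
.primary_entity <- function(term) {
  if (!is.null(term$entity)) return(term$entity)
  for (inner in term$inner) {
    e <- .primary_entity(inner)
    if (!is.null(e)) return(e)
  }
  NULL
}

.ns_key <- function(ns) paste0(ns$namespace, ":", ns$id)

# all namespaced entities in a statement or term, as "NS:id" keys
.collect_entities <- function(x) {
  if (inherits(x, "bel_statement"))
    return(c(.collect_entities(x$subject), .collect_entities(x$object)))
  out <- character(0)
  if (!is.null(x$entity)) out <- .ns_key(x$entity)
  for (m in x$mods)
    for (arg in m$args)
      if (inherits(arg, "bel_ns")) out <- c(out, .ns_key(arg))
  for (inner in x$inner) out <- c(out, .collect_entities(inner))
  out
}

.violation <- function(code, path, message) {
  list(code = code, path = path, message = message)
}

.check_term <- function(term, path, allowed_keys) {
  v <- list()
  fn <- term$fn
  if (fn %in% c("p", "g", "r", "a") && is.null(term$entity))
    v <- c(v, list(.violation("structural", path,
      sprintf("%s() requires a namespaced entity", fn))))
  if (fn == "act") {
    if (length(term$inner) != 1L)
      v <- c(v, list(.violation("structural", path,
        "act() requires exactly one inner term")))
    n_ma <- sum(vapply(term$mods, function(m) m$kind == "ma", logical(1)))
    if (n_ma > 1L)
      v <- c(v, list(.violation("structural", path,
        "act() allows at most one ma() modification")))
  }
  if (fn == "complex" && is.null(term$entity) && length(term$inner) < 2L)
    v <- c(v, list(.violation("structural", path,
      "complex() needs a named entity or at least two members")))
  if (fn %in% c("deg", "tloc") && length(term$inner) != 1L)
    v <- c(v, list(.violation("structural", path,
      sprintf("%s() requires exactly one inner term", fn))))
  if (.term_depth(term) > 4L)
    v <- c(v, list(.violation("structural", path,
      "term nesting exceeds the maximum depth of 4")))
  for (m in term$mods) {
    if (m$kind == "pmod") {
      if (length(m$args) < 1L || length(m$args) > 3L)
        v <- c(v, list(.violation("structural", path,
          "pmod() takes 1 to 3 arguments")))
      if (length(m$args) == 3L) {
        pos <- suppressWarnings(as.integer(as.character(m$args[[3L]])))
        if (is.na(pos) || pos <= 0L)
          v <- c(v, list(.violation("structural", path,
            "pmod() position must be a positive integer")))
      }
    }
  }
  if (!is.null(allowed_keys)) {
    for (key in unique(.collect_entities_local(term)))
      if (!key %in% allowed_keys)
        v <- c(v, list(.violation("ungrounded entity", path,
          sprintf("entity %s is not in the allow-list", key))))
  }
  for (i in seq_along(term$inner))
    v <- c(v, .check_term(term$inner[[i]],
                          paste0(path, "/inner[", i, "]"), allowed_keys))
  v
}

# entities at this term level only (inner terms handled by recursion)
.collect_entities_local <- function(term) {
  out <- character(0)
  if (!is.null(term$entity)) out <- .ns_key(term$entity)
  for (m in term$mods)
    for (arg in m$args)
      if (inherits(arg, "bel_ns")) out <- c(out, .ns_key(arg))
  out
}

#' Validate a BEL statement against structural rules and an allow-list
#'
#' Checks the structural invariants of the subset (function arities, pmod
#' argument rules, maximum nesting depth) and, when `allowed` is non-empty,
#' that every namespaced entity appears in the allow-list. The allow-list
#' check is the guard against hallucinated identifiers in LLM output.
#'
#' @param statement A [bel_statement()].
#' @param allowed Allow-list of groundings: a character vector of
#'   `"NAMESPACE:id"` keys, a data frame with `namespace` and `identifier`
#'   columns (as returned by [build_allowlist()]), or `NULL`/empty to skip
#'   the namespace check.
#' @return A list of violations, each `list(code, path, message)`; empty
#'   when the statement is fully valid. Violations are data, not errors.
#' @export
validate_statement <- function(statement, allowed = NULL) {
  stopifnot(inherits(statement, "bel_statement"))
  keys <- .allowlist_keys(allowed)
  c(.check_term(statement$subject, "subject", keys),
    .check_term(statement$object, "object", keys))
}

.allowlist_keys <- function(allowed) {
  if (is.null(allowed)) return(NULL)
  if (is.data.frame(allowed)) {
    if (nrow(allowed) == 0L) return(NULL)
    return(paste0(toupper(allowed$namespace), ":", allowed$identifier))
  }
  if (length(allowed) == 0L) return(NULL)
  as.character(allowed)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_bel(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", .serialize_term(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bel_statement <- function(x, ...) serialize_bel(x)
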