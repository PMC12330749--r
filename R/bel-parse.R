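# Recursive-descent parser and canonical serializer for the BEL subset.
#
# Grammar (whitespace allowed between any two tokens):
#   statement := term relation term
#   term      := FUNC "(" arg ("," arg)* ")"
#   arg       := term | modification | nsid | token
#   mod       := MODKIND "(" (nsid | token) ("," (nsid | token))* ")"
#   nsid      := IDENT ":" (IDENT | STRING)
# STRING is double-quoted, backslash escapes; curly quotes from typeset
# text are accepted and normalized to straight quotes.

.tokenize_bel <- function(text) {
  text <- chartr("“”", "\"\"", text)
  n <- nchar(text)
  toks <- list()
  i <- 1L
  ident_chars <- "[A-Za-z0-9_.+-]"
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",", ":")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\" && j < n) {
          buf <- c(buf, substr(text, j + 1L, j + 1L))
          j <- j + 2L
        } else if (cj == "\"") {
          closed <- TRUE
          j <- j + 1L
          break
        } else {
          buf <- c(buf, cj)
          j <- j + 1L
        }
      }
      if (!closed)
        .bel_error(sprintf("unterminated string at offset %d", i),
                   "bel_syntax_error", offset = i)
      toks[[length(toks) + 1L]] <- list(type = "STRING",
                                        value = paste0(buf, collapse = ""),
                                        pos = i)
      i <- j
      next
    }
    if (grepl(paste0("^", ident_chars, "$"), ch)) {
      j <- i
      while (j <= n && grepl(paste0("^", ident_chars, "$"),
                             substr(text, j, j))) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "IDENT",
                                        value = substr(text, i, j - 1L),
                                        pos = i)
      i <- j
      next
    }
    .bel_error(sprintf("unexpected character '%s' at offset %d", ch, i),
               "bel_syntax_error", offset = i)
  }
  toks
}

# parser state: token list plus cursor, mutated via environment
.ps <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

.peek <- function(st, ahead = 0L) {
  idx <- st$i + ahead
  if (idx > length(st$tokens)) return(NULL)
  st$tokens[[idx]]
}

.advance <- function(st) {
  tok <- .peek(st)
  st$i <- st$i + 1L
  tok
}

.expect <- function(st, type) {
  tok <- .peek(st)
  if (is.null(tok))
    .bel_error(sprintf("unexpected end of input, expected '%s'", type),
               "bel_syntax_error", offset = NA_integer_)
  if (tok$type != type)
    .bel_error(sprintf("expected '%s' but found '%s' at offset %d",
                       type, tok$value, tok$pos),
               "bel_syntax_error", offset = tok$pos)
  .advance(st)
}

.parse_nsid <- function(st) {
  ns_tok <- .expect(st, "IDENT")
  .expect(st, ":")
  id_tok <- .peek(st)
  if (is.null(id_tok) || !id_tok$type %in% c("IDENT", "STRING"))
    .bel_error(sprintf("expected identifier after '%s:' at offset %d",
                       ns_tok$value, ns_tok$pos),
               "bel_syntax_error", offset = ns_tok$pos)
  .advance(st)
  ns <- toupper(ns_tok$value)
  if (!ns %in% bel_namespaces())
    .bel_error(sprintf("unknown namespace '%s' at offset %d",
                       ns_tok$value, ns_tok$pos),
               "bel_unknown_namespace", offset = ns_tok$pos)
  bel_ns(ns, id_tok$value)
}

.parse_mod <- function(st) {
  kind_tok <- .expect(st, "IDENT")
  .expect(st, "(")
  args <- list()
  repeat {
    tok <- .peek(st)
    if (is.null(tok))
      .bel_error("unexpected end of input inside modification",
                 "bel_syntax_error", offset = NA_integer_)
    nxt <- .peek(st, 1L)
    if (tok$type == "IDENT" && !is.null(nxt) && nxt$type == ":") {
      args[[length(args) + 1L]] <- .parse_nsid(st)
    } else if (tok$type %in% c("IDENT", "STRING")) {
      .advance(st)
      args[[length(args) + 1L]] <- tok$value
    } else {
      .bel_error(sprintf("unexpected '%s' at offset %d in modification",
                         tok$value, tok$pos),
                 "bel_syntax_error", offset = tok$pos)
    }
    sep <- .peek(st)
    if (!is.null(sep) && sep$type == ",") { .advance(st); next }
    break
  }
  .expect(st, ")")
  bel_mod(kind_tok$value, args)
}

.parse_term <- function(st) {
  fn_tok <- .expect(st, "IDENT")
  if (!fn_tok$value %in% bel_functions())
    .bel_error(sprintf("unknown BEL function '%s' at offset %d",
                       fn_tok$value, fn_tok$pos),
               "bel_unknown_function", offset = fn_tok$pos)
  .expect(st, "(")
  entity <- NULL
  inner <- list()
  mods <- list()
  repeat {
    tok <- .peek(st)
    if (is.null(tok))
      .bel_error("unexpected end of input inside term",
                 "bel_syntax_error", offset = NA_integer_)
    if (tok$type == ")") break
    nxt <- .peek(st, 1L)
    if (tok$type == "IDENT" && !is.null(nxt) && nxt$type == "(") {
      if (tok$value %in% .BEL_MOD_KINDS) {
        mods[[length(mods) + 1L]] <- .parse_mod(st)
      } else if (tok$value %in% bel_functions()) {
        inner[[length(inner) + 1L]] <- .parse_term(st)
      } else {
        .bel_error(sprintf("unknown BEL function '%s' at offset %d",
                           tok$value, tok$pos),
                   "bel_unknown_function", offset = tok$pos)
      }
    } else if (tok$type == "IDENT" && !is.null(nxt) && nxt$type == ":") {
      ns <- .parse_nsid(st)
      if (!is.null(entity))
        .bel_error(sprintf(
          "unexpected second namespaced entity at offset %d", tok$pos),
          "bel_syntax_error", offset = tok$pos)
      entity <- ns
    } else {
      .bel_error(sprintf("unexpected '%s' at offset %d in term",
                         tok$value, tok$pos),
                 "bel_syntax_error", offset = tok$pos)
    }
    sep <- .peek(st)
    if (!is.null(sep) && sep$type == ",") { .advance(st); next }
    break
  }
  .expect(st, ")")
  bel_term(fn_tok$value, entity = entity, inner = inner, mods = mods)
}

#' Parse a BEL statement string
#'
#' Parses the subject-predicate-object surface syntax of the supported BEL
#' subset into a [bel_statement()] tree. Whitespace between tokens is
#' ignored and typographic (curly) quotes are accepted.
#'
#' @param text A single BEL statement string, e.g.
#'   `'p(HGNC:TP53) increases p(HGNC:MDM2)'`.
#' @return A [bel_statement()].
#' @details Errors are typed conditions: `bel_syntax_error` (with a
#'   character `offset` field), `bel_unknown_function`,
#'   `bel_unknown_relation`, `bel_unknown_namespace`.
#' @examples
#' s <- parse_bel('act(p(HGNC:AKT1), ma(GO:"kinase activity"))
#'                directlyIncreases p(HGNC:HSF1, pmod(Ph, Ser, 326))')
#' serialize_bel(s)
#' @export
parse_bel <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text)))
    .bel_error("empty BEL statement", "bel_syntax_error", offset = 1L)
  st <- .ps(.tokenize_bel(text))
  subject <- .parse_term(st)
  rel_tok <- .peek(st)
  if (is.null(rel_tok) || rel_tok$type != "IDENT")
    .bel_error("expected a relation after the subject term",
               "bel_syntax_error",
               offset = if (is.null(rel_tok)) NA_integer_ else rel_tok$pos)
  .advance(st)
  if (!rel_tok$value %in% bel_relations())
    .bel_error(sprintf("unknown relation '%s' at offset %d",
                       rel_tok$value, rel_tok$pos),
               "bel_unknown_relation", offset = rel_tok$pos)
  object <- .parse_term(st)
  trailing <- .peek(st)
  if (!is.null(trailing))
    .bel_error(sprintf("unexpected trailing input at offset %d",
                       trailing$pos),
               "bel_syntax_error", offset = trailing$pos)
  bel_statement(subject, rel_tok$value, object)
}

.serialize_id <- function(id) {
  if (grepl("[^A-Za-z0-9_]", id) || !nzchar(id)) {
    escaped <- gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", id))
    paste0("\"", escaped, "\"")
  } else id
}

.serialize_ns <- function(ns) paste0(ns$namespace, ":", .serialize_id(ns$id))

.serialize_mod <- function(mod) {
  parts <- vapply(mod$args, function(a) {
    if (inherits(a, "bel_ns")) .serialize_ns(a) else as.character(a)
  }, character(1))
  paste0(mod$kind, "(", paste0(parts, collapse = ","), ")")
}

.serialize_term <- function(term) {
  parts <- character(0)
  if (!is.null(term$entity)) parts <- .serialize_ns(term$entity)
  parts <- c(parts, vapply(term$inner, .serialize_term, character(1)))
  parts <- c(parts, vapply(term$mods, .serialize_mod, character(1)))
  paste0(term$fn, "(", paste0(parts, collapse = ","), ")")
}

#' Serialize a BEL statement to its canonical string
#'
#' The canonical form is deterministic: no spaces after commas, entity
#' before inner terms before modifications, names quoted exactly when they
#' contain characters outside `[A-Za-z0-9_]`, namespaces uppercased. Two
#' statements are structurally equal if and only if their canonical strings
#' are equal, which makes the canonical string usable as a node identity
#' key in graph construction.
#'
#' @param statement A [bel_statement()].
#' @return A single character string.
#' @export
serialize_bel <- function(statement) {
  stopifnot(inherits(statement, "bel_statement"))
  paste(.serialize_term(statement$subject), statement$relation,
        .serialize_term(statement$object))
}

#' Canonical string of a single BEL term
#'
#' @param term A [bel_term()].
#' @return A single character string.
#' @export
serialize_bel_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  .serialize_term(term)
}
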