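# Named-entity grounding: map text mentions to namespace:identifier pairs
# through a pluggable grounder contract. The offline dictionary grounder
# keeps the full pipeline runnable with no network; a live grounding
# service client satisfies the same contract.

#' Construct an entity annotation
#'
#' @param matched_text The mention as it appears in the paragraph.
#' @param start,end 0-based half-open character offsets into the paragraph
#'   text, so that `substr(text, start + 1, end) == matched_text`.
#' @param namespace,identifier The grounding, e.g. `HGNC` / `AKT1`.
#' @param name Canonical name of the grounded entity.
#' @param score Grounder confidence in `[0, 1]`.
#' @param source Name of the grounder that produced the annotation.
#' @return Object of class `entity_annotation`.
#' @export
entity_annotation <- function(matched_text, start, end, namespace,
                              identifier, name = matched_text,
                              score = 1.0, source = "dictionary") {
  stopifnot(is.numeric(start), is.numeric(end), end > start,
            score >= 0, score <= 1)
  structure(list(matched_text = matched_text, start = as.integer(start),
                 end = as.integer(end), namespace = toupper(namespace),
                 identifier = identifier, name = name, score = score,
                 source = source),
            class = "entity_annotation")
}

#' @export
print.entity_annotation <- function(x, ...) {
  cat(sprintf("<entity_annotation> [%d,%d) '%s' -> %s:%s (%.2f)\n",
              x$start, x$end, x$matched_text, x$namespace, x$identifier,
              x$score))
  invisible(x)
}

#' Load the packaged mini-lexicon
#'
#' A small dictionary of HGNC gene symbols plus a few GO and CHEBI names,
#' sufficient to ground the bundled fixture articles offline.
#'
#' @return Data frame with columns `term`, `namespace`, `identifier`,
#'   `name`.
#' @export
load_mini_lexicon <- function() {
  path <- system.file("extdata", "mini_lexicon.tsv",
                      package = "beltograph")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Offline dictionary grounder
#'
#' Implements the grounder contract — `ground(text)` returning candidate
#' matches `{matched_text, start, end, namespace, identifier, name,
#' score}` — by exact and case-insensitive whole-word lookup against a
#' term dictionary. Exact matches score 1.0, case-insensitive matches 0.8.
#'
#' @param lexicon Data frame with columns `term`, `namespace`,
#'   `identifier`, `name`; defaults to the packaged mini-lexicon.
#' @return A grounder list with `ground` and `name` fields.
#' @export
dictionary_grounder <- function(lexicon = load_mini_lexicon()) {
  stopifnot(all(c("term", "namespace", "identifier", "name") %in%
                  names(lexicon)))
  ground <- function(text) {
    out <- list()
    for (k in seq_len(nrow(lexicon))) {
      term <- lexicon$term[k]
      pattern <- paste0("(?<![A-Za-z0-9_])", .regex_escape(term),
                        "(?![A-Za-z0-9_])")
      for (ignore_case in c(FALSE, TRUE)) {
        hits <- gregexpr(pattern, text, perl = TRUE,
                         ignore.case = ignore_case)[[1]]
        if (hits[1] == -1L) next
        lens <- attr(hits, "match.length")
        for (h in seq_along(hits)) {
          start <- as.integer(hits[h]) - 1L
          matched <- substr(text, start + 1L, start + lens[h])
          exact <- identical(matched, term)
          if (ignore_case && exact) next  # already found in exact pass
          out[[length(out) + 1L]] <- entity_annotation(
            matched_text = matched, start = start, end = start + lens[h],
            namespace = lexicon$namespace[k],
            identifier = lexicon$identifier[k],
            name = lexicon$name[k],
            score = if (exact) 1.0 else 0.8,
            source = "dictionary")
        }
      }
    }
    out
  }
  list(name = "dictionary", ground = ground)
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.spans_overlap <- function(a, b) a$start < b$end && b$start < a$end

#' Ground a paragraph's entity mentions
#'
#' Runs the injected grounder over the paragraph text and resolves
#' overlapping candidate matches: the highest-scoring candidate wins, ties
#' go to the longest span, remaining ties to the earliest start. The
#' result is sorted by start offset.
#'
#' @param paragraph A paragraph object (with `text` and `index` fields) or
#'   a plain character string.
#' @param grounder A grounder contract, e.g. [dictionary_grounder()].
#' @return List of [entity_annotation()] objects.
#' @export
ground_paragraph <- function(paragraph, grounder) {
  text <- if (is.character(paragraph)) paragraph else paragraph$text
  idx <- if (is.character(paragraph)) NA_integer_ else paragraph$index
  candidates <- tryCatch(grounder$ground(text), error = function(e)
    .bel_error(sprintf("grounder failed on paragraph %s: %s",
                       idx, conditionMessage(e)),
               "bel_grounder_error", paragraph_index = idx))
  if (length(candidates) == 0L) return(list())
  score <- vapply(candidates, `[[`, numeric(1), "score")
  len <- vapply(candidates, function(a) a$end - a$start, integer(1))
  start <- vapply(candidates, `[[`, integer(1), "start")
  ord <- order(-score, -len, start)
  kept <- list()
  for (i in ord) {
    cand <- candidates[[i]]
    clash <- any(vapply(kept, .spans_overlap, logical(1), b = cand))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept[order(vapply(kept, `[[`, integer(1), "start"))]
}

#' Build an entity allow-list from annotations
#'
#' Deduplicates annotation groundings into the allow-list handed to the
#' extraction prompt and to [validate_statement()], in first-appearance
#' order.
#'
#' @param annotations List of [entity_annotation()] objects.
#' @return Data frame with columns `namespace`, `identifier`, `name`,
#'   `key` (`"NAMESPACE:identifier"`), zero rows for empty input.
#' @export
build_allowlist <- function(annotations) {
  empty <- data.frame(namespace = character(0), identifier = character(0),
                      name = character(0), key = character(0),
                      stringsAsFactors = FALSE)
  if (length(annotations) == 0L) return(empty)
  df <- data.frame(
    namespace = vapply(annotations, `[[`, character(1), "namespace"),
    identifier = vapply(annotations, `[[`, character(1), "identifier"),
    name = vapply(annotations, `[[`, character(1), "name"),
    stringsAsFactors = FALSE)
  df$key <- paste0(df$namespace, ":", df$identifier)
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}
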