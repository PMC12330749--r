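# Statement extraction: build a BEL-syntax prompt with the grounded
# allow-list, drive the LLM backend per paragraph, and validate/repair
# the structured output into evidence records. Unparseable output gets
# exactly one repair round-trip, then is quarantined with its error.

.PROMPT_GUIDE <- paste(
  "You extract molecular interactions from scientific text as statements",
  "in Biological Expression Language (BEL).",
  "A BEL statement has the form: subject relation object.",
  "Terms are functional expressions over namespaced entities:",
  "  p(HGNC:AKT1)                 a protein",
  "  g(HGNC:TP53) / r(HGNC:TP53)  a gene / an RNA",
  "  a(CHEBI:\"NAD(+)\")            a chemical abundance",
  "  act(p(HGNC:AKT1), ma(GO:\"kinase activity\"))  a molecular activity",
  "  p(HGNC:HSF1, pmod(Ph, Ser, 326))  a modified protein",
  "  complex(p(HGNC:A), p(HGNC:B))     a molecular complex",
  "  bp(GO:\"DNA repair\") / path(DOID:...)  a process / pathology",
  "Relations: increases, decreases, directlyIncreases, directlyDecreases,",
  "association, regulates.",
  "Use ONLY entities from the allowed-identifier list below; never invent",
  "identifiers. For each interaction, return the BEL statement and the",
  "exact sentence from the paragraph it was extracted from as evidence.",
  sep = "\n")

#' Build the extraction prompt for a paragraph
#'
#' Assembles the BEL syntax guide, the rendered allow-list of grounded
#' identifiers (one `NAMESPACE:ID  (name)` line per entry), and the
#' paragraph text. The result is deterministic given its inputs.
#'
#' @param paragraph A paragraph object or character string.
#' @param annotations List of [entity_annotation()] objects for the
#'   paragraph.
#' @return Object of class `extraction_prompt` with fields `system_text`,
#'   `paragraph_text`, `annotations_text`, `paragraph_index`; `format()`
#'   renders the full prompt text.
#' @export
build_prompt <- function(paragraph, annotations = list()) {
  text <- if (is.character(paragraph)) paragraph else paragraph$text
  idx <- if (is.character(paragraph)) NA_integer_ else paragraph$index
  allow <- build_allowlist(annotations)
  ann_text <- if (nrow(allow) == 0L) {
    paste("No pre-annotated entities were found in this paragraph.",
          "Extract statements only when you can ground every entity in a",
          "standard namespace without guessing; otherwise return nothing.")
  } else {
    paste0("Allowed identifiers:\n",
           paste(sprintf("%s:%s  (%s)", allow$namespace, allow$identifier,
                         allow$name), collapse = "\n"))
  }
  structure(list(system_text = .PROMPT_GUIDE,
                 paragraph_text = text,
                 annotations_text = ann_text,
                 paragraph_index = idx),
            class = "extraction_prompt")
}

#' @export
format.extraction_prompt <- function(x, ...) {
  paste(x$system_text, x$annotations_text,
        paste0("Paragraph:\n", x$paragraph_text), sep = "\n\n")
}

#' @export
print.extraction_prompt <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.split_sentences <- function(text) {
  out <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  out[nzchar(trimws(out))]
}

.norm_for_match <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# normalized similarity in [0,1] between an evidence string and the best
# matching sentence of the paragraph
.evidence_similarity <- function(evidence, paragraph_text) {
  sentences <- .split_sentences(paragraph_text)
  if (length(sentences) == 0L) return(0)
  ev <- .norm_for_match(evidence)
  best <- 0
  for (s in .norm_for_match(sentences)) {
    d <- utils::adist(ev, s)
    sim <- 1 - d / max(nchar(ev), nchar(s), 1L)
    if (sim > best) best <- sim
  }
  best
}

#' Construct an evidence record
#'
#' @param statement A parsed [bel_statement()].
#' @param evidence_sentence The sentence supporting the statement.
#' @param paragraph_index 0-based paragraph position.
#' @param source_id Article identifier or file path.
#' @param violations Validation violations attached to the record.
#' @param repaired Whether the statement went through a repair round-trip.
#' @return Object of class `evidence_record`.
#' @export
evidence_record <- function(statement, evidence_sentence, paragraph_index,
                            source_id, violations = list(),
                            repaired = FALSE) {
  stopifnot(inherits(statement, "bel_statement"))
  structure(list(statement = statement,
                 evidence_sentence = evidence_sentence,
                 paragraph_index = as.integer(paragraph_index),
                 source_id = source_id,
                 violations = violations,
                 repaired = isTRUE(repaired)),
            class = "evidence_record")
}

#' @export
print.evidence_record <- function(x, ...) {
  cat("<evidence_record> ", serialize_bel(x$statement), "\n  evidence: ",
      x$evidence_sentence, "\n  violations: ", length(x$violations),
      "\n", sep = "")
  invisible(x)
}

.process_raw <- function(raw, prompt, allow, paragraph, backend,
                         evidence_threshold) {
  parse_try <- function(bel) tryCatch(parse_bel(bel), error = identity)
  stmt <- parse_try(raw$bel_statement %||% "")
  repaired <- FALSE
  if (inherits(stmt, "error") && !is.null(backend$repair)) {
    fix <- tryCatch(
      backend$repair(prompt, raw, conditionMessage(stmt)),
      error = function(e) NULL)
    if (!is.null(fix)) {
      stmt2 <- parse_try(fix$bel_statement %||% "")
      if (!inherits(stmt2, "error")) {
        stmt <- stmt2
        raw <- fix
        repaired <- TRUE
      }
    }
  }
  if (inherits(stmt, "error")) {
    return(list(record = NULL, quarantine = list(
      raw = raw, error = conditionMessage(stmt),
      paragraph_index = paragraph$index)))
  }
  violations <- validate_statement(stmt, allow)
  evidence <- raw$evidence %||% ""
  if (!nzchar(trimws(evidence))) {
    violations <- c(violations, list(.violation(
      "evidence fidelity", "evidence", "evidence sentence is empty")))
  } else if (.evidence_similarity(evidence, paragraph$text) <
               evidence_threshold) {
    violations <- c(violations, list(.violation(
      "evidence fidelity", "evidence",
      "evidence sentence does not match any paragraph sentence")))
  }
  list(record = evidence_record(stmt, evidence, paragraph$index,
                                paragraph$source_id,
                                violations = violations,
                                repaired = repaired),
       quarantine = NULL)
}

#' Extract BEL statements from one paragraph
#'
#' Sends the paragraph and its allow-list to the backend, parses every
#' returned statement, applies structural and allow-list validation, and
#' checks evidence fidelity against the paragraph's sentences. A statement
#' that fails to parse triggers exactly one repair call to the backend
#' (the parser error is passed along); if it still fails it is
#' quarantined with the raw payload retained. Statements that parse but
#' carry violations (ungrounded entities, paraphrased evidence) are
#' retained with their violations recorded, not dropped, so a reviewer can
#' inspect them.
#'
#' @param paragraph A paragraph object.
#' @param annotations List of [entity_annotation()]s for the paragraph.
#' @param backend An LLM backend contract, e.g. [stub_backend()].
#' @param evidence_threshold Minimum normalized similarity between the
#'   claimed evidence sentence and its best-matching paragraph sentence
#'   (case/whitespace-insensitive) before a "paraphrased evidence"
#'   violation is recorded.
#' @return `list(records =, quarantined =)`.
#' @export
extract_paragraph <- function(paragraph, annotations, backend,
                              evidence_threshold = 0.9) {
  prompt <- build_prompt(paragraph, annotations)
  allow <- build_allowlist(annotations)
  raws <- backend$complete(prompt)
  records <- list()
  quarantined <- list()
  for (raw in raws) {
    res <- .process_raw(raw, prompt, allow, paragraph, backend,
                        evidence_threshold)
    if (!is.null(res$record))
      records[[length(records) + 1L]] <- res$record
    else
      quarantined[[length(quarantined) + 1L]] <- res$quarantine
  }
  list(records = records, quarantined = quarantined)
}

#' Extract BEL statements from a whole document
#'
#' Grounds each paragraph, runs [extract_paragraph()] per paragraph in
#' document order and concatenates the results. A failure in one
#' paragraph (backend transport error, grounder error) never aborts the
#' document: the error is recorded in the run report and the remaining
#' paragraphs are processed.
#'
#' @param doc An `article_document` (typically already passed through
#'   [filter_paragraphs()]).
#' @param grounder A grounder contract; `NULL` reuses pre-annotations
#'   carried on the paragraphs (e.g. from BioC XML).
#' @param backend An LLM backend contract.
#' @param evidence_threshold Passed to [extract_paragraph()].
#' @return `list(records, quarantined, report)` where `report` holds
#'   per-paragraph extraction counts and any per-paragraph errors.
#' @export
extract_document <- function(doc, grounder, backend,
                             evidence_threshold = 0.9) {
  stopifnot(inherits(doc, "article_document"))
  records <- list()
  quarantined <- list()
  per_paragraph <- list()
  errors <- list()
  for (p in doc$paragraphs) {
    res <- tryCatch({
      anns <- if (is.null(grounder)) p$annotations
              else ground_paragraph(p, grounder)
      extract_paragraph(p, anns, backend, evidence_threshold)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(
        paragraph_index = p$index, message = conditionMessage(res))
      per_paragraph[[length(per_paragraph) + 1L]] <- list(
        paragraph_index = p$index, n_records = 0L, n_quarantined = 0L,
        failed = TRUE)
      next
    }
    records <- c(records, res$records)
    quarantined <- c(quarantined, res$quarantined)
    per_paragraph[[length(per_paragraph) + 1L]] <- list(
      paragraph_index = p$index,
      n_records = length(res$records),
      n_quarantined = length(res$quarantined),
      failed = FALSE)
  }
  list(records = records, quarantined = quarantined,
       report = list(source_id = doc$source_id,
                     n_paragraphs = length(doc$paragraphs),
                     n_records = length(records),
                     n_quarantined = length(quarantined),
                     per_paragraph = per_paragraph,
                     errors = errors))
}

#' Write evidence records as BEL-as-JSON
#'
#' The BEL-as-JSON dialect is a JSON array of objects with fields
#' `source_id`, `paragraph_index`, `paragraph_text` (optional),
#' `bel_statement` (canonical string), `evidence`, `violations`.
#'
#' @param records List of [evidence_record()]s.
#' @param path Output file path.
#' @param doc Optional `article_document` used to attach paragraph text.
#' @return `path`, invisibly.
#' @export
write_bel_json <- function(records, path, doc = NULL) {
  para_text <- function(r) {
    if (is.null(doc)) return(NULL)
    for (p in doc$paragraphs)
      if (p$index == r$paragraph_index) return(p$text)
    NULL
  }
  payload <- lapply(records, function(r) {
    obj <- list(source_id = r$source_id,
                paragraph_index = r$paragraph_index,
                bel_statement = serialize_bel(r$statement),
                evidence = r$evidence_sentence,
                violations = lapply(r$violations, function(v)
                  list(code = v$code, path = v$path,
                       message = v$message)))
    pt <- para_text(r)
    if (!is.null(pt)) obj$paragraph_text <- pt
    obj
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read BEL-as-JSON evidence records
#'
#' Parses each record's BEL statement; records whose statements fail to
#' parse are quarantined rather than aborting the read.
#'
#' @param path Path to a BEL-as-JSON file.
#' @return `list(records =, quarantined =)`.
#' @export
read_bel_json <- function(path) {
  if (!file.exists(path))
    .bel_error(sprintf("file '%s' does not exist", path), "bel_not_found")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- list()
  quarantined <- list()
  for (obj in payload) {
    stmt <- tryCatch(parse_bel(obj$bel_statement %||% ""),
                     error = identity)
    if (inherits(stmt, "error")) {
      quarantined[[length(quarantined) + 1L]] <- list(
        raw = obj, error = conditionMessage(stmt),
        paragraph_index = obj$paragraph_index %||% NA_integer_)
      next
    }
    violations <- lapply(obj$violations %||% list(), function(v)
      .violation(v$code, v$path, v$message))
    records[[length(records) + 1L]] <- evidence_record(
      stmt, obj$evidence %||% "",
      obj$paragraph_index %||% NA_integer_,
      obj$source_id %||% NA_character_,
      violations = violations)
  }
  list(records = records, quarantined = quarantined)
}
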