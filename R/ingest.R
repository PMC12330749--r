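# Input resolution: PMC identifiers via an injected article-service client
# (BioC-style XML), or local text/markdown files. Both paths produce the
# same article_document contract consumed downstream.

.normalize_text <- function(x) {
  x <- enc2utf8(x)
  # NFC normalization + control character stripping
  x <- stringi_nfc(x)
  x <- gsub("[\\x01-\\x08\\x0b\\x0c\\x0e-\\x1f\\x7f]", "", x, perl = TRUE)
  gsub("[ \t]+", " ", trimws(x))
}

# iconv-based NFC; stringi is not a dependency
stringi_nfc <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "UTF-8")
  out[is.na(out)] <- x[is.na(out)]
  out
}

.paragraph <- function(text, section, index, source_id,
                       annotations = list()) {
  structure(list(text = text, section = section, index = index,
                 source_id = source_id, annotations = annotations),
            class = "bel_paragraph")
}

.article_document <- function(source_id, title, paragraphs) {
  structure(list(source_id = source_id, title = title,
                 paragraphs = paragraphs),
            class = "article_document")
}

#' @export
print.article_document <- function(x, ...) {
  cat("<article_document> ", x$source_id, ": ",
      length(x$paragraphs), " paragraph(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.article_document <- function(x, ...) {
  data.frame(
    index = vapply(x$paragraphs, `[[`, integer(1), "index"),
    section = vapply(x$paragraphs, `[[`, character(1), "section"),
    text = vapply(x$paragraphs, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
}

# re-pack paragraph indices to 0-based contiguous order
.repack_indices <- function(paragraphs) {
  for (i in seq_along(paragraphs)) paragraphs[[i]]$index <- i - 1L
  paragraphs
}

#' Article-service client over local BioC XML files
#'
#' The client contract is a list with a single function `get(pmcid)`
#' returning BioC XML text. This implementation reads from a directory of
#' `<pmcid>.xml` files (or a named character vector of file paths), so tests
#' and offline runs never touch the network.
#'
#' @param dir Directory containing `<pmcid>.xml` files, or a named
#'   character vector mapping pmcids to file paths.
#' @return A client list with a `get` function.
#' @export
bioc_client_file <- function(dir) {
  get_path <- function(pmcid) {
    if (is.character(dir) && !is.null(names(dir)) && pmcid %in% names(dir))
      return(dir[[pmcid]])
    file.path(dir, paste0(pmcid, ".xml"))
  }
  list(get = function(pmcid) {
    path <- get_path(pmcid)
    if (!file.exists(path))
      .bel_error(sprintf("article '%s' not found", pmcid),
                 "bel_not_found")
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
          collapse = "\n")
  })
}

#' Article-service client backed by the packaged fixture article
#'
#' Serves the bundled BioC-style XML fixture for any requested pmcid, for
#' offline demonstration and testing.
#'
#' @return A client list with a `get` function.
#' @export
bioc_client_fixture <- function() {
  path <- system.file("extdata", "fixture_article.xml",
                      package = "beltograph")
  list(get = function(pmcid) {
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
          collapse = "\n")
  })
}

.parse_bioc_annotations <- function(passage_node, passage_text,
                                    passage_offset) {
  anns <- list()
  for (ann in xml2::xml_find_all(passage_node, "./annotation")) {
    loc <- xml2::xml_find_first(ann, "./location")
    if (is.na(xml2::xml_name(loc))) next
    off <- as.integer(xml2::xml_attr(loc, "offset"))
    len <- as.integer(xml2::xml_attr(loc, "length"))
    ident <- xml2::xml_text(xml2::xml_find_first(
      ann, "./infon[@key='identifier']"))
    txt <- xml2::xml_text(xml2::xml_find_first(ann, "./text"))
    start <- off - passage_offset
    if (is.na(start) || start < 0L) next
    parts <- strsplit(ident, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !toupper(parts[1]) %in% bel_namespaces())
      next
    span <- substr(passage_text, start + 1L, start + len)
    if (!identical(span, txt)) {
      # offsets drifted under text normalization; relocate the mention
      hit <- regexpr(txt, passage_text, fixed = TRUE)
      if (hit == -1L) next
      start <- as.integer(hit) - 1L
      len <- nchar(txt)
    }
    anns[[length(anns) + 1L]] <- entity_annotation(
      matched_text = txt, start = start, end = start + len,
      namespace = toupper(parts[1]), identifier = parts[2],
      name = txt, score = 1.0, source = "bioc")
  }
  anns
}

#' Fetch an article as a paragraph-segmented document
#'
#' Resolves a PMC identifier through an injected article-service client and
#' parses the returned BioC-style XML into an ordered paragraph list.
#' Entity annotations present in the XML are carried through as
#' pre-annotations on each paragraph. Passages with empty text are dropped
#' and indices re-packed.
#'
#' @param pmcid Identifier matching `PMC\\d+`.
#' @param client Article-service client, e.g. [bioc_client_file()] or
#'   [bioc_client_fixture()].
#' @return An `article_document`.
#' @export
fetch_article <- function(pmcid, client) {
  if (!grepl("^PMC[0-9]+$", pmcid))
    .bel_error(sprintf("'%s' is not a valid PMC identifier", pmcid),
               "bel_precondition_error")
  xml_text <- client$get(pmcid)
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e)
    .bel_error(sprintf("malformed XML for %s: %s", pmcid,
                       conditionMessage(e)), "bel_parse_error"))
  title <- NA_character_
  paragraphs <- list()
  for (passage in xml2::xml_find_all(doc, "//passage")) {
    sec <- xml2::xml_text(xml2::xml_find_first(
      passage, "./infon[@key='section_type']"))
    typ <- xml2::xml_text(xml2::xml_find_first(
      passage, "./infon[@key='type']"))
    off_node <- xml2::xml_find_first(passage, "./offset")
    off <- if (is.na(xml2::xml_name(off_node))) 0L else
      as.integer(xml2::xml_text(off_node))
    raw_text <- xml2::xml_text(xml2::xml_find_first(passage, "./text"))
    if (is.na(raw_text)) raw_text <- ""
    text <- .normalize_text(raw_text)
    if (!is.na(typ) && typ %in% c("front", "title") && is.na(title))
      title <- text
    if (!nzchar(text)) next
    anns <- .parse_bioc_annotations(passage, text, off)
    paragraphs[[length(paragraphs) + 1L]] <- .paragraph(
      text = text,
      section = if (is.na(sec)) "UNKNOWN" else toupper(sec),
      index = 0L, source_id = pmcid, annotations = anns)
  }
  .article_document(pmcid, title, .repack_indices(paragraphs))
}

.looks_like_heading <- function(line) {
  line <- trimws(line)
  if (grepl("^#{1,6}\\s+", line)) return(TRUE)
  nzchar(line) && nchar(line) <= 60 && !grepl("[.!?]$", line) &&
    identical(line, toupper(line)) && grepl("[A-Z]", line)
}

.heading_label <- function(line) {
  line <- trimws(sub("^#{1,6}\\s+", "", trimws(line)))
  toupper(gsub("[^A-Za-z0-9 ]", "", line))
}

#' Read a local text or markdown file as a document
#'
#' Paragraphs are split on blank lines. Markdown headings (`#`) and short
#' all-caps lines are treated as section labels for the paragraphs that
#' follow them.
#'
#' @param path Path to a plain text or markdown file.
#' @return An `article_document` with `source_id` equal to `path`.
#' @export
read_local <- function(path) {
  if (!file.exists(path))
    .bel_error(sprintf("file '%s' does not exist", path), "bel_not_found")
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (any(raw == as.raw(0L)))
    .bel_error(sprintf("file '%s' appears to be binary", path),
               "bel_parse_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    .bel_error(sprintf("file '%s' is empty", path), "bel_parse_error")
  section <- "BODY"
  title <- NA_character_
  paragraphs <- list()
  buf <- character(0)
  flush_buf <- function() {
    if (length(buf) == 0L) return()
    text <- .normalize_text(paste(buf, collapse = " "))
    if (nzchar(text))
      paragraphs[[length(paragraphs) + 1L]] <<- .paragraph(
        text = text, section = section, index = 0L, source_id = path)
    buf <<- character(0)
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) { flush_buf(); next }
    if (.looks_like_heading(line)) {
      flush_buf()
      section <- .heading_label(line)
      if (is.na(title)) title <- trimws(sub("^#{1,6}\\s+", "", trimws(line)))
      next
    }
    buf <- c(buf, line)
  }
  flush_buf()
  .article_document(path, title, .repack_indices(paragraphs))
}

#' Default section blocklist for rules-based paragraph filtering
#'
#' Section labels dropped by [filter_paragraphs()] in `rules` mode:
#' bibliography and administrative back matter that carries no extractable
#' molecular interactions.
#'
#' @return Character vector of uppercase section labels.
#' @export
default_section_blocklist <- function() {
  c("REF", "REFERENCES", "BIBLIOGRAPHY", "ACK", "ACKNOWLEDGMENTS",
    "ACKNOWLEDGEMENTS", "FUNDING", "AUTH_CONT", "AUTHOR CONTRIBUTIONS",
    "COMP_INT", "CONFLICT OF INTEREST", "SUPPL", "APPENDIX")
}

#' Filter a document down to extraction-relevant paragraphs
#'
#' `rules` mode drops paragraphs whose section label (or leading words)
#' match a blocklist of non-content sections such as references and
#' acknowledgments; it is deterministic and the default. `llm` mode
#' delegates the keep/drop decision to an injected backend per paragraph,
#' mirroring pipelines that use a language model for relevance triage.
#' Retained paragraphs keep their relative order and are re-indexed.
#'
#' @param doc An `article_document`.
#' @param mode `"rules"` or `"llm"`.
#' @param backend For `llm` mode: a backend with a `keep(paragraph)`
#'   function returning `TRUE`/`FALSE`.
#' @param blocklist Uppercase section labels to drop in `rules` mode.
#' @return A filtered `article_document`.
#' @export
filter_paragraphs <- function(doc, mode = c("rules", "llm"),
                              backend = NULL,
                              blocklist = default_section_blocklist()) {
  mode <- match.arg(mode)
  stopifnot(inherits(doc, "article_document"))
  keep <- logical(length(doc$paragraphs))
  if (mode == "rules") {
    for (i in seq_along(doc$paragraphs)) {
      p <- doc$paragraphs[[i]]
      lead <- toupper(trimws(substr(p$text, 1, 40)))
      blocked <- toupper(p$section) %in% blocklist ||
        any(startsWith(lead, blocklist))
      keep[i] <- !blocked
    }
  } else {
    if (is.null(backend))
      .bel_error("llm filtering mode requires a backend",
                 "bel_precondition_error")
    for (i in seq_along(doc$paragraphs)) {
      p <- doc$paragraphs[[i]]
      keep[i] <- tryCatch(isTRUE(backend$keep(p)), error = function(e)
        .bel_error(sprintf("backend failed on paragraph %d: %s",
                           p$index, conditionMessage(e)),
                   "bel_backend_error", paragraph_index = p$index))
    }
  }
  .article_document(doc$source_id, doc$title,
                    .repack_indices(doc$paragraphs[keep]))
}
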