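# Component-level statement comparison. Two BEL statements are compared
# on their canonical subject term, relation and object term; each matching
# scored component earns its weight and the total is the sum. Namespace
# agreement of the subject/object primary entities is tracked separately
# and never scored, since it measures a weaker kind of agreement.

#' Default sub-score weights for statement comparison
#'
#' The relation carries 0.4 of the total; the remainder is split evenly
#' between subject and object so the maximum score over all three
#' components is exactly 1.
#'
#' @return Named numeric vector with entries `subject`, `relation`,
#'   `object`.
#' @export
default_weights <- function() {
  c(subject = 0.3, relation = 0.4, object = 0.3)
}

#' Compare two BEL statements component by component
#'
#' Subject, relation and object are compared on canonical forms (exact
#' canonical-string equality for terms, case-sensitive equality for
#' relations). The total score is the sum of the weights of matching
#' components: identical statements score 1, fully disjoint statements 0,
#' and statements agreeing only on the relation score the relation weight
#' (0.4 by default). Namespace-only agreement of the subject and object
#' primary entities is reported in separate booleans and does not enter
#' the score.
#'
#' @param a,b [bel_statement()] objects.
#' @param weights Named weights summing to 1; see [default_weights()].
#' @return Object of class `comparison_result` with fields
#'   `subject_match`, `relation_match`, `object_match`,
#'   `subject_ns_match`, `object_ns_match`, `total_score`, `judge`
#'   (`NA` until set), and the two statements.
#' @export
compare_statements <- function(a, b, weights = default_weights()) {
  stopifnot(inherits(a, "bel_statement"), inherits(b, "bel_statement"))
  if (!all(c("subject", "relation", "object") %in% names(weights)))
    .bel_error("weights must name subject, relation and object",
               "bel_value_error")
  if (abs(sum(weights[c("subject", "relation", "object")]) - 1) > 1e-9)
    .bel_error("weights must sum to 1", "bel_value_error")
  subject_match <- .serialize_term(a$subject) == .serialize_term(b$subject)
  relation_match <- a$relation == b$relation
  object_match <- .serialize_term(a$object) == .serialize_term(b$object)
  ns_of <- function(term) {
    e <- .primary_entity(term)
    if (is.null(e)) NA_character_ else e$namespace
  }
  ns_eq <- function(x, y) !is.na(x) && !is.na(y) && x == y
  total <- sum(weights[c("subject", "relation", "object")] *
                 c(subject_match, relation_match, object_match))
  structure(list(a = a, b = b,
                 subject_match = subject_match,
                 relation_match = relation_match,
                 object_match = object_match,
                 subject_ns_match = ns_eq(ns_of(a$subject), ns_of(b$subject)),
                 object_ns_match = ns_eq(ns_of(a$object), ns_of(b$object)),
                 total_score = unname(total),
                 judge = NA_character_),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> total=%.2f (subject=%s relation=%s object=%s)\n",
    x$total_score, x$subject_match, x$relation_match, x$object_match))
  invisible(x)
}

#' Find the best-matching candidate statement
#'
#' Scores the query against every candidate with [compare_statements()]
#' and returns the candidate with the highest total score; ties are broken
#' by candidate order (the first of the tied candidates wins).
#'
#' @param query A [bel_statement()].
#' @param candidates Non-empty list of [bel_statement()]s.
#' @param weights Passed to [compare_statements()].
#' @return `list(candidate =, result =, index =)`.
#' @export
best_match <- function(query, candidates, weights = default_weights()) {
  if (length(candidates) == 0L)
    .bel_error("candidates must be non-empty", "bel_precondition_error")
  best_i <- 1L
  best_res <- compare_statements(query, candidates[[1L]], weights)
  if (length(candidates) > 1L) {
    for (i in 2L:length(candidates)) {
      res <- compare_statements(query, candidates[[i]], weights)
      if (res$total_score > best_res$total_score) {
        best_i <- i
        best_res <- res
      }
    }
  }
  list(candidate = candidates[[best_i]], result = best_res,
       index = best_i)
}

#' Aggregate component agreement over compared pairs
#'
#' Counts matching subjects, relations, objects and namespace-only
#' agreements across a list of comparison results, with fractions reported
#' both raw and as percentages rounded to one decimal (the conventional
#' reporting format, e.g. 6 of 29 pairs = 20.7%).
#'
#' @param pairs List of `comparison_result` objects.
#' @return Object of class `agreement_report`: `n_pairs`, per-component
#'   `counts`, `fractions`, `percent`, and `judge_counts`. With zero
#'   pairs, fractions and percentages are `NA` (undefined), not 0.
#' @export
aggregate_agreement <- function(pairs) {
  components <- c("subject_match", "relation_match", "object_match",
                  "subject_ns_match", "object_ns_match")
  n <- length(pairs)
  counts <- vapply(components, function(comp)
    sum(vapply(pairs, function(p) isTRUE(p[[comp]]), logical(1))),
    integer(1))
  fractions <- if (n == 0L) rep(NA_real_, length(components)) else
    counts / n
  names(fractions) <- components
  judge_labels <- vapply(pairs, function(p)
    if (is.null(p$judge)) NA_character_ else p$judge, character(1))
  judge_counts <- c(Good = sum(judge_labels == "Good", na.rm = TRUE),
                    Medium = sum(judge_labels == "Medium", na.rm = TRUE),
                    Bad = sum(judge_labels == "Bad", na.rm = TRUE))
  structure(list(n_pairs = n, counts = counts, fractions = fractions,
                 percent = round(100 * fractions, 1),
                 judge_counts = judge_counts),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$n_pairs, " pair(s)\n", sep = "")
  if (x$n_pairs == 0L) {
    cat("  fractions undefined (no pairs)\n")
    return(invisible(x))
  }
  lab <- c(subject_match = "matching subjects",
           relation_match = "matching relationship types",
           object_match = "matching objects",
           subject_ns_match = "subject namespace agreement",
           object_ns_match = "object namespace agreement")
  for (comp in names(lab))
    cat(sprintf("  %d of %d (%.1f%%) %s\n", x$counts[[comp]], x$n_pairs,
                x$percent[[comp]], lab[[comp]]))
  if (sum(x$judge_counts) > 0)
    cat("  judge:", paste(names(x$judge_counts), x$judge_counts,
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

.JUDGE_RUBRIC <- paste(
  "Rate the semantic similarity of two BEL statements extracted from the",
  "same evidence text using exactly one of three categories:",
  "Good, representing the same relationship; Medium, where statements are",
  "related but differ slightly in specificity; and Bad, where statements",
  "describe different relationships.",
  "Answer with the single word Good, Medium or Bad.",
  sep = "\n")

#' Judge the semantic similarity of two extracted statements
#'
#' Builds a rubric prompt (Good = same relationship; Medium = related but
#' differing in specificity; Bad = different relationships) over the two
#' statements and their shared evidence, and asks the backend to pick a
#' category. A backend answer outside the three-category vocabulary is a
#' typed error, never silently coerced.
#'
#' @param a,b [evidence_record()]s sharing evidence text.
#' @param backend An LLM backend with a `judge(prompt)` function;
#'   [stub_backend()] scripts the answer for offline runs.
#' @return One of `"Good"`, `"Medium"`, `"Bad"`.
#' @export
judge_similarity <- function(a, b, backend) {
  stopifnot(inherits(a, "evidence_record"), inherits(b, "evidence_record"))
  prompt <- list(
    rubric = .JUDGE_RUBRIC,
    statement_a = serialize_bel(a$statement),
    statement_b = serialize_bel(b$statement),
    evidence = a$evidence_sentence)
  label <- backend$judge(prompt)
  if (!is.character(label) || length(label) != 1L ||
      !label %in% c("Good", "Medium", "Bad"))
    .bel_error(sprintf("judge returned out-of-vocabulary label '%s'",
                       paste(label, collapse = ",")),
               "bel_judge_error")
  label
}

#' Load externally produced BEL statements for comparison
#'
#' Reads a BEL-as-JSON file of statements keyed by evidence text (e.g.
#' another extraction system's output converted to BEL) into evidence
#' records. Records whose BEL fails to parse are quarantined per record,
#' not fatal.
#'
#' @param path Path to a BEL-as-JSON file.
#' @return `list(records =, quarantined =)`.
#' @export
load_external_bel <- function(path) read_bel_json(path)

.norm_evidence_key <- function(x) .norm_for_match(x)

#' Pair two record sets by shared evidence text and score them
#'
#' For every evidence text (case/whitespace-insensitively normalized) that
#' both sets produced statements for, each statement of `ours` is paired
#' with its [best_match()] among the `theirs` statements sharing that
#' evidence. Evidence texts present in only one set contribute no pairs.
#'
#' @param ours,theirs Lists of [evidence_record()]s.
#' @param weights Passed to [compare_statements()].
#' @param judge_backend Optional backend; when supplied each pair is also
#'   rated with [judge_similarity()].
#' @return `list(pairs = list of comparison_result, report =
#'   agreement_report, n_shared_evidence =)`.
#' @export
compare_record_sets <- function(ours, theirs, weights = default_weights(),
                                judge_backend = NULL) {
  key_of <- function(r) .norm_evidence_key(r$evidence_sentence)
  theirs_by_key <- split(theirs, vapply(theirs, key_of, character(1)))
  pairs <- list()
  shared <- character(0)
  for (r in ours) {
    key <- key_of(r)
    cands <- theirs_by_key[[key]]
    if (is.null(cands) || length(cands) == 0L) next
    shared <- union(shared, key)
    bm <- best_match(r$statement,
                     lapply(cands, `[[`, "statement"), weights)
    res <- bm$result
    if (!is.null(judge_backend))
      res$judge <- judge_similarity(r, cands[[bm$index]], judge_backend)
    pairs[[length(pairs) + 1L]] <- res
  }
  list(pairs = pairs, report = aggregate_agreement(pairs),
       n_shared_evidence = length(shared))
}
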