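# LLM backend contracts. Every LLM-dependent stage (paragraph triage,
# statement extraction, repair, similarity judging) talks to a backend
# object rather than a vendor API, so the pipeline is testable and
# bit-reproducible offline. A backend is a list providing any of:
#   complete(prompt)          -> list of raw extractions
#                                list(bel_statement=, evidence=)
#   repair(prompt, raw, err)  -> a single raw extraction or NULL
#   keep(paragraph)           -> TRUE/FALSE (paragraph triage)
#   judge(prompt)             -> one of "Good", "Medium", "Bad"

#' Deterministic scripted LLM backend
#'
#' Plays back pre-scripted structured responses keyed by paragraph index,
#' for offline runs and tests. The script is a named list whose keys are
#' paragraph indices as character strings (`"0"`, `"1"`, ...); each value
#' is a list of raw extractions, each a `list(bel_statement =, evidence =)`.
#' Repairs are looked up under `"<index>:repair"`, judge labels under
#' `"judge"` (a character vector consumed in order), and triage decisions
#' under `"keep"` (a logical vector indexed by paragraph index + 1).
#'
#' @param script Named list of scripted responses.
#' @return A backend list implementing the contract functions.
#' @seealso [stub_backend_from_file()] to load a script from JSON.
#' @export
stub_backend <- function(script = list()) {
  judge_cursor <- 0L
  backend <- new.env(parent = emptyenv())
  backend$calls <- list()

  complete <- function(prompt) {
    key <- as.character(prompt$paragraph_index)
    backend$calls[[length(backend$calls) + 1L]] <- list(
      type = "complete", key = key)
    raws <- script[[key]]
    if (is.null(raws)) return(list())
    lapply(raws, function(r)
      list(bel_statement = r$bel_statement, evidence = r$evidence))
  }
  repair <- function(prompt, raw, error_message) {
    key <- paste0(as.character(prompt$paragraph_index), ":repair")
    backend$calls[[length(backend$calls) + 1L]] <- list(
      type = "repair", key = key)
    fixes <- script[[key]]
    if (is.null(fixes)) return(NULL)
    # match the repair to the broken statement when several are scripted
    for (f in fixes)
      if (is.null(f$broken) || identical(f$broken, raw$bel_statement))
        return(list(bel_statement = f$bel_statement,
                    evidence = f$evidence %||% raw$evidence))
    NULL
  }
  keep <- function(paragraph) {
    keeps <- script[["keep"]]
    if (is.null(keeps)) return(TRUE)
    isTRUE(keeps[[paragraph$index + 1L]])
  }
  judge <- function(prompt) {
    labels <- script[["judge"]]
    if (is.null(labels)) return("Good")
    judge_cursor <<- judge_cursor + 1L
    labels[[min(judge_cursor, length(labels))]]
  }
  list(name = "stub", complete = complete, repair = repair,
       keep = keep, judge = judge, state = backend)
}

#' Load a scripted stub backend from a JSON file
#'
#' @param path Path to a JSON object with the [stub_backend()] script
#'   layout.
#' @return A backend list.
#' @export
stub_backend_from_file <- function(path) {
  script <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(script$keep))
    script$keep <- vapply(script$keep, isTRUE, logical(1))
  if (!is.null(script$judge))
    script$judge <- vapply(script$judge, as.character, character(1))
  stub_backend(script)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Mock NDEx client
#'
#' Satisfies the network-exchange client contract (`save_network(cx2)`)
#' by recording the payload and returning a fixed network identifier.
#' Useful for testing [upload_network()] without a live service.
#'
#' @param id Identifier the mock returns.
#' @param authenticated Whether the mock behaves as authenticated.
#' @return A client list with `save_network` and a `state` environment
#'   whose `last_payload` holds the most recent upload.
#' @export
mock_ndex_client <- function(id = "mock-network-0001",
                             authenticated = TRUE) {
  state <- new.env(parent = emptyenv())
  state$last_payload <- NULL
  list(
    state = state,
    save_network = function(cx2) {
      if (!authenticated)
        .bel_error("NDEx authentication failed", "bel_auth_error")
      state$last_payload <- cx2
      id
    }
  )
}
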