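akt_paragraph <- function() {
  make_paragraph(paste(
    "The kinase activity of AKT1 phosphorylates HSF1 at serine 326.",
    "Phosphorylated HSF1 is more active."))
}

akt_statement_text <- function() {
  paste0('act(p(HGNC:AKT1),ma(GO:"kinase activity")) directlyIncreases ',
         "p(HGNC:HSF1,pmod(Ph,Ser,326))")
}

test_that("prompts render every allow-list entry once and are deterministic", {
  p <- akt_paragraph()
  anns <- ground_paragraph(p, dictionary_grounder())
  prompt <- build_prompt(p, anns)
  allow <- build_allowlist(anns)
  for (k in seq_len(nrow(allow))) {
    line <- sprintf("%s:%s  (%s)", allow$namespace[k],
                    allow$identifier[k], allow$name[k])
    hits <- gregexpr(line, prompt$annotations_text, fixed = TRUE)[[1]]
    expect_identical(length(hits[hits > 0]), 1L)
  }
  # byte-identical across two calls with the same inputs
  expect_identical(format(build_prompt(p, anns)), format(prompt))
  # no annotations: the prompt says so and warns against invented ids
  empty_prompt <- build_prompt(make_paragraph("Plain text."), list())
  expect_match(empty_prompt$annotations_text, "No pre-annotated entities")
})

test_that("a scripted extraction of the AKT1-HSF1 statement yields one clean record", {
  p <- akt_paragraph()
  anns <- ground_paragraph(p, dictionary_grounder())
  backend <- stub_backend(list("0" = list(list(
    bel_statement = akt_statement_text(),
    evidence = "The kinase activity of AKT1 phosphorylates HSF1 at serine 326."))))
  out <- extract_paragraph(p, anns, backend)
  expect_length(out$records, 1)
  expect_length(out$quarantined, 0)
  rec <- out$records[[1]]
  expect_identical(serialize_bel(rec$statement), akt_statement_text())
  expect_identical(rec$violations, list())
  expect_false(rec$repaired)
})

test_that("a broken statement is repaired once, then quarantined if still broken", {
  p <- akt_paragraph()
  broken <- "act(p(HGNC:AKT1) directlyIncreases p(HGNC:HSF1)"
  backend <- stub_backend(list(
    "0" = list(list(bel_statement = broken,
                    evidence = "Phosphorylated HSF1 is more active.")),
    "0:repair" = list(list(
      broken = broken,
      bel_statement = "act(p(HGNC:AKT1)) directlyIncreases p(HGNC:HSF1)"))))
  out <- extract_paragraph(p, list(), backend)
  expect_length(out$records, 1)
  expect_true(out$records[[1]]$repaired)
  calls <- vapply(backend$state$calls, `[[`, character(1), "type")
  expect_identical(sum(calls == "repair"), 1L)

  hopeless <- stub_backend(list(
    "0" = list(list(bel_statement = "not bel at all(", evidence = "x"))))
  out2 <- extract_paragraph(p, list(), hopeless)
  expect_length(out2$records, 0)
  expect_length(out2$quarantined, 1)
  expect_identical(out2$quarantined[[1]]$raw$bel_statement,
                   "not bel at all(")
  expect_match(out2$quarantined[[1]]$error, ".")
})

test_that("out-of-allow-list entities are retained with a violation, not dropped", {
  p <- akt_paragraph()
  anns <- ground_paragraph(p, dictionary_grounder())
  backend <- stub_backend(list("0" = list(list(
    bel_statement = "p(HGNC:BRCA1) increases p(HGNC:HSF1)",
    evidence = "Phosphorylated HSF1 is more active."))))
  out <- extract_paragraph(p, anns, backend)
  expect_length(out$records, 1)
  v <- out$records[[1]]$violations
  codes <- vapply(v, `[[`, character(1), "code")
  expect_true("ungrounded entity" %in% codes)
  # cross-check against the validator directly
  expect_identical(
    codes[codes == "ungrounded entity"],
    vapply(validate_statement(out$records[[1]]$statement,
                              build_allowlist(anns)),
           `[[`, character(1), "code"))
})

test_that("paraphrased evidence is flagged while near-verbatim evidence passes", {
  p <- akt_paragraph()
  near <- "the kinase activity of AKT1  phosphorylates HSF1 at serine 326."
  backend <- stub_backend(list("0" = list(
    list(bel_statement = "p(HGNC:AKT1) increases p(HGNC:HSF1)",
         evidence = near),
    list(bel_statement = "p(HGNC:AKT1) increases p(HGNC:HSF1)",
         evidence = "AKT1 is a kinase that acts on many substrates."))))
  out <- extract_paragraph(p, list(), backend)
  expect_length(out$records, 2)
  codes1 <- vapply(out$records[[1]]$violations, `[[`, character(1), "code")
  codes2 <- vapply(out$records[[2]]$violations, `[[`, character(1), "code")
  expect_false("evidence fidelity" %in% codes1)
  expect_true("evidence fidelity" %in% codes2)
})

test_that("document extraction is additive, order-preserving and failure-isolated", {
  doc <- make_document(c("AKT1 activates HSF1.", "TP53 induces MDM2.",
                         "SIRT1 consumes NAD+."))
  script <- list(
    "0" = list(list(bel_statement = "p(HGNC:AKT1) increases p(HGNC:HSF1)",
                    evidence = "AKT1 activates HSF1.")),
    "2" = list(list(bel_statement = "p(HGNC:TP53) increases p(HGNC:MDM2)",
                    evidence = "SIRT1 consumes NAD+."),
               list(bel_statement = "p(HGNC:MDM2) decreases p(HGNC:TP53)",
                    evidence = "SIRT1 consumes NAD+.")))
  backend <- stub_backend(script)
  run <- extract_document(doc, dictionary_grounder(), backend)
  per <- vapply(run$report$per_paragraph, `[[`, integer(1), "n_records")
  expect_identical(sum(per), length(run$records))
  expect_identical(per, c(1L, 0L, 2L))
  expect_identical(
    vapply(run$records, `[[`, integer(1), "paragraph_index"),
    c(0L, 2L, 2L))

  # one failing paragraph never aborts the document
  flaky <- backend
  flaky$complete <- function(prompt) {
    if (prompt$paragraph_index == 1L) stop("transport error")
    backend$complete(prompt)
  }
  run2 <- extract_document(doc, dictionary_grounder(), flaky)
  expect_length(run2$records, 3)
  expect_length(run2$report$errors, 1)
  expect_identical(run2$report$errors[[1]]$paragraph_index, 1L)
})

test_that("quarantine completeness: raws = records + quarantined", {
  doc <- make_document(c("AKT1 activates HSF1.", "TP53 induces MDM2."))
  script <- list(
    "0" = list(
      list(bel_statement = "p(HGNC:AKT1) increases p(HGNC:HSF1)",
           evidence = "AKT1 activates HSF1."),
      list(bel_statement = "garbage(((", evidence = "x")),
    "1" = list(
      list(bel_statement = "p(HGNC:TP53) increases p(HGNC:MDM2)",
           evidence = "TP53 induces MDM2.")))
  n_raws <- sum(vapply(script, length, integer(1)))
  run <- extract_document(doc, dictionary_grounder(),
                          stub_backend(script))
  expect_identical(length(run$records) + length(run$quarantined), n_raws)
  expect_identical(run$report$n_quarantined, 1L)
})

test_that("BEL-as-JSON round-trips records with provenance and violations", {
  doc <- make_document(c("AKT1 activates HSF1 strongly."))
  backend <- stub_backend(list("0" = list(list(
    bel_statement = "p(HGNC:AKT1) increases p(HGNC:FAKE9)",
    evidence = "AKT1 activates HSF1 strongly."))))
  run <- extract_document(doc, dictionary_grounder(), backend)
  path <- withr::local_tempfile(fileext = ".json")
  write_bel_json(run$records, path, doc = doc)
  loaded <- read_bel_json(path)
  expect_length(loaded$records, 1)
  rec <- loaded$records[[1]]
  expect_identical(serialize_bel(rec$statement),
                   serialize_bel(run$records[[1]]$statement))
  expect_identical(rec$evidence_sentence,
                   run$records[[1]]$evidence_sentence)
  expect_identical(rec$paragraph_index, 0L)
  expect_identical(
    vapply(rec$violations, `[[`, character(1), "code"),
    vapply(run$records[[1]]$violations, `[[`, character(1), "code"))
  # a corrupt statement in the file is quarantined on read
  payload <- jsonlite::read_json(path)
  payload[[2]] <- payload[[1]]
  payload[[2]]$bel_statement <- "((broken"
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, path2, auto_unbox = TRUE)
  loaded2 <- read_bel_json(path2)
  expect_length(loaded2$records, 1)
  expect_length(loaded2$quarantined, 1)
})
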