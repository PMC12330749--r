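test_that("identical statements score 1, disjoint 0, relation-only 0.4", {
  worked <- parse_bel(paste(
    'act(p(HGNC:AKT1), ma(GO:"kinase activity")) directlyIncreases',
    "p(HGNC:HSF1, pmod(Ph, Ser, 326))"))
  expect_identical(compare_statements(worked, worked)$total_score, 1)

  a <- parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)")
  b <- parse_bel("p(HGNC:TP53) increases p(HGNC:MDM2)")
  rel_only <- compare_statements(a, b)
  expect_identical(rel_only$total_score, 0.4)
  expect_false(rel_only$subject_match)
  expect_true(rel_only$relation_match)
  expect_false(rel_only$object_match)

  d <- parse_bel("p(HGNC:TP53) decreases p(HGNC:MDM2)")
  none <- compare_statements(a, d)
  expect_identical(none$total_score, 0)
})

test_that("namespace-only agreement is tracked but never scored", {
  a <- parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)")
  b <- parse_bel("p(HGNC:TP53) decreases p(HGNC:MDM2)")
  res <- compare_statements(a, b)
  expect_true(res$subject_ns_match)
  expect_true(res$object_ns_match)
  expect_identical(res$total_score, 0)
  # entity-free terms have no namespace to agree on
  c2 <- parse_bel("p(HGNC:AKT1) increases bp(GO:\"DNA repair\")")
  d2 <- parse_bel("p(HGNC:TP53) decreases p(HGNC:MDM2)")
  res2 <- compare_statements(c2, d2)
  expect_false(res2$object_ns_match)
})

test_that("custom weights are honored and invalid weights rejected", {
  a <- parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)")
  b <- parse_bel("p(HGNC:AKT1) decreases p(HGNC:HSF1)")
  w <- c(subject = 0.5, relation = 0.2, object = 0.3)
  expect_equal(compare_statements(a, b, w)$total_score, 0.8)
  expect_error(
    compare_statements(a, b, c(subject = 0.5, relation = 0.5,
                               object = 0.5)),
    class = "bel_value_error")
})

test_that("scores are symmetric, bounded, and extreme exactly at full/no match", {
  pool <- statement_pool()
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      f <- compare_statements(pool[[i]], pool[[j]])
      r <- compare_statements(pool[[j]], pool[[i]])
      expect_identical(f$total_score, r$total_score)
      expect_gte(f$total_score, 0)
      expect_lte(f$total_score, 1)
      all_match <- f$subject_match && f$relation_match && f$object_match
      none_match <- !f$subject_match && !f$relation_match &&
        !f$object_match
      expect_identical(f$total_score == 1, all_match)
      expect_identical(f$total_score == 0, none_match)
    }
  }
})

test_that("best_match agrees with a brute-force argmax oracle on 50 random sets", {
  set.seed(404)
  pool <- statement_pool()
  for (trial in 1:50) {
    query <- pool[[sample(length(pool), 1)]]
    cands <- pool[sample(length(pool), sample(2:6, 1), replace = TRUE)]
    got <- best_match(query, cands)
    expect_identical(got$index, argmax_oracle(query, cands))
    expect_identical(serialize_bel(got$candidate),
                     serialize_bel(cands[[got$index]]))
  }
  # single candidate and exact-duplicate cases
  one <- best_match(pool[[1]], pool[1])
  expect_identical(one$index, 1L)
  dup <- best_match(pool[[1]], list(pool[[2]], pool[[1]], pool[[1]]))
  expect_identical(dup$index, 2L)
  expect_identical(dup$result$total_score, 1)
  expect_error(best_match(pool[[1]], list()),
               class = "bel_precondition_error")
})

test_that("a 29-pair corpus with 6/11/8 matches reports 20.7/37.9/27.6 percent", {
  # engineer exactly 6 subject, 11 relation, 8 object matches out of 29
  ref <- parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)")
  make_pair <- function(subj, rel, obj) {
    other <- bel_statement(
      if (subj) ref$subject else bel_term("p", bel_ns("HGNC", "TP53")),
      if (rel) "increases" else "decreases",
      if (obj) ref$object else bel_term("p", bel_ns("HGNC", "MDM2")))
    compare_statements(ref, other)
  }
  flags <- data.frame(
    subj = rep(c(TRUE, FALSE), c(6, 23)),
    rel = rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 2, 7, 16)),
    obj = rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 10, 5, 11)))
  pairs <- lapply(seq_len(29), function(i)
    make_pair(flags$subj[i], flags$rel[i], flags$obj[i]))
  rep_out <- aggregate_agreement(pairs)
  expect_identical(rep_out$n_pairs, 29L)
  expect_identical(unname(rep_out$counts[c("subject_match",
                                           "relation_match",
                                           "object_match")]),
                   c(6L, 11L, 8L))
  expect_identical(unname(rep_out$percent[c("subject_match",
                                            "relation_match",
                                            "object_match")]),
                   c(20.7, 37.9, 27.6))
  # brute-force recount straight off the comparison objects
  expect_identical(unname(rep_out$counts[["subject_match"]]),
                   sum(vapply(pairs, `[[`, logical(1), "subject_match")))
  expect_identical(unname(rep_out$counts[["relation_match"]]),
                   sum(vapply(pairs, `[[`, logical(1), "relation_match")))
  expect_identical(unname(rep_out$counts[["object_match"]]),
                   sum(vapply(pairs, `[[`, logical(1), "object_match")))
})

test_that("zero pairs report undefined fractions, not zeros", {
  rep_out <- aggregate_agreement(list())
  expect_identical(rep_out$n_pairs, 0L)
  expect_true(all(is.na(rep_out$fractions)))
  expect_true(all(is.na(rep_out$percent)))
})

test_that("the judge passes scripted categories through and rejects out-of-vocabulary labels", {
  a <- evidence_record(parse_bel("p(HGNC:AKT1) increases p(HGNC:HSF1)"),
                       "shared evidence", 0L, "d1")
  b <- evidence_record(parse_bel("act(p(HGNC:AKT1)) increases p(HGNC:HSF1)"),
                       "shared evidence", 0L, "d2")
  expect_identical(
    judge_similarity(a, b, stub_backend(list(judge = "Medium"))),
    "Medium")
  expect_error(
    judge_similarity(a, b, stub_backend(list(judge = "Excellent"))),
    class = "bel_judge_error")
})

test_that("external BEL files load with per-record quarantine and pair by shared evidence", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(source_id = "indra", paragraph_index = 0,
         bel_statement = "p(HGNC:AKT1) increases p(HGNC:HSF1)",
         evidence = "Sentence A."),
    list(source_id = "indra", paragraph_index = 1,
         bel_statement = "p(HGNC:TP53) decreases p(HGNC:MDM2)",
         evidence = "Sentence B."),
    list(source_id = "indra", paragraph_index = 2,
         bel_statement = "((not bel", evidence = "Sentence C.")),
    path, auto_unbox = TRUE)
  loaded <- load_external_bel(path)
  expect_length(loaded$records, 2)
  expect_length(loaded$quarantined, 1)

  ours <- list(
    evidence_record(parse_bel("act(p(HGNC:AKT1)) increases p(HGNC:HSF1)"),
                    "Sentence A.", 0L, "ours"),
    evidence_record(parse_bel("p(HGNC:PARP1) increases bp(GO:\"DNA repair\")"),
                    "Sentence unshared.", 1L, "ours"))
  cmp <- compare_record_sets(ours, loaded$records)
  # set-intersection oracle: only evidence texts both sets produced
  shared <- intersect(
    tolower(vapply(ours, `[[`, character(1), "evidence_sentence")),
    tolower(vapply(loaded$records, `[[`, character(1),
                   "evidence_sentence")))
  expect_identical(cmp$n_shared_evidence, length(shared))
  expect_length(cmp$pairs, 1)
  expect_true(cmp$pairs[[1]]$relation_match)
})
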