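dec_row <- function(doc, h, t, level, decision) {
  tibble::tibble(doc_id = doc, head_id = h, tail_id = t, level = level,
                 decision = decision, score = 0.5, span_text = NA_character_)
}

test_that("merging fires on any positive instance and deduplicates", {
  d <- dplyr::bind_rows(
    dec_row("d1", "c1", "d1", "intra", FALSE),
    dec_row("d1", "c1", "d1", "inter", TRUE),
    dec_row("d1", "c1", "d2", "intra", FALSE),
    dec_row("d1", "c1", "d2", "intra", FALSE),
    dec_row("d2", "c1", "d1", "inter", TRUE),
    dec_row("d2", "c1", "d1", "inter", TRUE))
  m <- merge_predictions(d)
  expect_equal(nrow(m), 3)
  expect_true(m$positive[m$doc_id == "d1" & m$tail_id == "d1"])
  expect_false(m$positive[m$doc_id == "d1" & m$tail_id == "d2"])
  expect_equal(m$provenance[m$doc_id == "d2"], "inter")
  # order independence
  m2 <- merge_predictions(d[sample(nrow(d)), ])
  expect_equal(as.data.frame(m), as.data.frame(m2))
  # idempotence on the merged representation
  m3 <- merge_predictions(dplyr::rename(m, decision = positive) |>
                            dplyr::mutate(level = "intra"))
  expect_equal(m3$positive, m$positive)
})

fallback_corpus <- function() {
  fixture_corpus(
    "A note on aspirin.",
    "Patients developed pain. Others developed nausea.",
    tibble::tibble(text = c("aspirin", "pain", "nausea"),
                   etype = c("chemical", "disease", "disease"),
                   concept_id = c("c1", "d1", "d2"))) |> split_sentences()
}

test_that("fallback pairs title chemicals with abstract diseases", {
  corp <- fallback_corpus()
  empty_cands <- tibble::tibble(doc_id = character())
  merged <- tibble::tibble(doc_id = character(), head_id = character(),
                           tail_id = character(), positive = logical(),
                           provenance = character())
  out <- apply_fallback(merged, corp, empty_cands)
  expect_equal(nrow(out), 2)
  expect_setequal(out$tail_id, c("d1", "d2"))
  expect_true(all(out$positive))
  expect_true(all(out$provenance == "fallback"))
})

test_that("fallback leaves documents with candidates untouched", {
  corp <- fallback_corpus()
  cands <- tibble::tibble(doc_id = "d1")  # the document produced a candidate
  merged <- tibble::tibble(doc_id = "d1", head_id = "c1", tail_id = "d1",
                           positive = FALSE, provenance = NA_character_)
  out <- apply_fallback(merged, corp, cands)
  expect_equal(as.data.frame(out), as.data.frame(merged))
})

test_that("fallback adds nothing without title chemicals", {
  corp <- fixture_corpus(
    "A note on outcomes.", "aspirin was given. Patients developed pain.",
    tibble::tibble(text = c("aspirin", "pain"),
                   etype = c("chemical", "disease"),
                   concept_id = c("c1", "d1"))) |> split_sentences()
  out <- apply_fallback(tibble::tibble(doc_id = character(),
                                       head_id = character(),
                                       tail_id = character(),
                                       positive = logical(),
                                       provenance = character()),
                        corp, tibble::tibble(doc_id = character()))
  expect_equal(nrow(out), 0)
})

test_that("precision, recall and F1 follow the set comparison", {
  gold <- tibble::tibble(doc_id = "d1", head_id = "c1",
                         tail_id = c("d1", "d2"))
  pred <- tibble::tibble(doc_id = "d1", head_id = "c1",
                         tail_id = c("d1", "d3"), positive = TRUE,
                         provenance = "intra")
  ev <- evaluate_pairs(pred, gold)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$f1, 0.5)
  expect_equal(ev$tp + ev$fn, nrow(gold))
  expect_equal(ev$tp + ev$fp, sum(pred$positive))
  # perfect prediction
  ev2 <- evaluate_pairs(dplyr::mutate(gold, positive = TRUE), gold)
  expect_equal(ev2$f1, 1)
  # degenerate convention: no positives at all
  ev3 <- evaluate_pairs(dplyr::mutate(gold, positive = FALSE), gold)
  expect_equal(c(ev3$precision, ev3$recall, ev3$f1), c(0, 0, 0))
})

test_that("duplicate gold pairs collapse with a warning", {
  gold <- tibble::tibble(doc_id = "d1", head_id = "c1", tail_id = c("d1", "d1"))
  pred <- tibble::tibble(doc_id = "d1", head_id = "c1", tail_id = "d1",
                         positive = TRUE, provenance = "intra")
  expect_warning(ev <- evaluate_pairs(pred, gold), "collapsed")
  expect_equal(ev$f1, 1)
})

test_that("level-restricted scores use candidates of that level only", {
  gold <- tibble::tibble(doc_id = "d1", head_id = "c1",
                         tail_id = c("d1", "d2", "d3"))
  lm <- tibble::tibble(doc_id = "d1", head_id = "c1",
                       tail_id = c("d1", "d2", "d3"),
                       level = c("intra", "inter", "inter"))
  pred <- tibble::tibble(doc_id = "d1", head_id = "c1",
                         tail_id = c("d1", "d2"), positive = TRUE,
                         provenance = c("intra", "inter"))
  ev <- evaluate_pairs(pred, gold, level_map = lm)
  expect_equal(ev$f1[ev$level == "intra"], 1)
  expect_equal(ev$recall[ev$level == "inter"], 0.5)
  expect_equal(ev$precision[ev$level == "inter"], 1)
})

test_that("fallback never lowers document-level recall", {
  syn <- small_synth(n_docs = 6, seed = 41)
  corp <- split_sentences(syn$corpus)
  cands <- extract_candidates(corp)
  # pretend the model predicted nothing positive
  merged <- dplyr::mutate(dplyr::distinct(
    cands[, c("doc_id", "head_id", "tail_id")]),
    positive = FALSE, provenance = NA_character_)
  before <- evaluate_pairs(merged, corp$gold_pairs)
  after <- evaluate_pairs(apply_fallback(merged, corp, cands),
                          corp$gold_pairs)
  expect_gte(after$recall, before$recall)
  expect_gte(nrow(apply_fallback(merged, corp, cands)), nrow(merged))
})
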