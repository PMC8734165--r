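test_that("toy document yields one intra and two inter candidates", {
  cands <- extract_candidates(toy_doc())
  expect_equal(nrow(cands), 3)
  c_d1 <- cands[cands$tail_id == "D1", ]
  expect_equal(c_d1$level, "intra")
  expect_equal(c_d1$distance, 0L)
  c_d2 <- cands[cands$tail_id == "D2", ]
  expect_equal(c_d2$level, "inter")
  expect_equal(c_d2$distance, 1L)
  c_d3 <- cands[cands$tail_id == "D3", ]
  expect_equal(c_d3$level, "inter")
  expect_equal(c_d3$distance, 3L)
})

test_that("pairs beyond the sentence-distance bound are dropped", {
  cands <- extract_candidates(toy_doc_far())
  expect_false("D3" %in% cands$tail_id)
  expect_setequal(cands$tail_id, c("D1", "D2"))
  # and the bound is configurable
  cands5 <- extract_candidates(toy_doc_far(), max_inter_distance = 5L)
  expect_true("D3" %in% cands5$tail_id)
})

test_that("an intra pair is never also emitted as inter", {
  corp <- fixture_corpus(
    "Aspirin therapy.", "Aspirin causes headache. Filler here. headache persisted.",
    tibble::tibble(text = c("Aspirin", "headache"),
                   etype = c("chemical", "disease"),
                   concept_id = c("C1", "D1"))) |> split_sentences()
  cands <- extract_candidates(corp)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$level, "intra")
})

test_that("unresolved (-1) mentions never enter candidate pairing", {
  corp <- fixture_corpus(
    "Aspirin study.", "Aspirin causes pain. Malaise was seen.",
    tibble::tibble(text = c("Aspirin", "pain", "Malaise"),
                   etype = c("chemical", "disease", "disease"),
                   concept_id = c("C1", "D1", "-1"))) |> split_sentences()
  cands <- extract_candidates(corp)
  expect_equal(cands$tail_id, "D1")
})

test_that("chr mode pairs chemicals over the full document context", {
  corp <- fixture_corpus(
    "Aspirin chemistry.", "Aspirin reacts slowly. Later salicylate formed.",
    tibble::tibble(text = c("Aspirin", "salicylate"),
                   etype = c("chemical", "chemical"),
                   concept_id = c("C1", "C2"))) |> split_sentences()
  cands <- extract_candidates(corp, chr_mode = TRUE)
  expect_setequal(paste(cands$head_id, cands$tail_id),
                  c("C1 C2", "C2 C1"))
  expect_true(all(cands$win_start == 0))
  expect_true(all(cands$win_end == nchar(corp$documents$text[1])))
})

test_that("masking replaces competing tail mentions and maps offsets back", {
  corp <- toy_doc()
  cands <- extract_candidates(corp)
  cands <- cands[order(cands$tail_id), ]
  masked <- mask_context(cands, corp)
  # intra candidate (C1, D1): its context sentence has no other disease
  expect_equal(masked$context[1], "Aspirin and headache.")
  # (C1, D2) window: sentences 1-2, contains headache (masked) and Nausea
  ctx2 <- masked$context[2]
  expect_false(grepl("headache", ctx2))
  expect_true(grepl("UNK", ctx2))
  expect_true(grepl("Nausea", ctx2))
  # kept tail mention maps back to its document span
  cm <- masked$ctx_mentions[[2]]
  nm <- cm[cm$concept_id == "D2", ]
  expect_equal(substr(corp$documents$text[1], nm$doc_start + 1, nm$doc_end),
               "Nausea")
  expect_equal(substr(ctx2, nm$ctx_start + 1, nm$ctx_end), "Nausea")
})

test_that("a context whose only tail-type mention is the tail is unchanged", {
  corp <- fixture_corpus(
    "Drug trial.", "Aspirin causes pain today.",
    tibble::tibble(text = c("Aspirin", "pain"),
                   etype = c("chemical", "disease"),
                   concept_id = c("C1", "D1"))) |> split_sentences()
  cands <- extract_candidates(corp)
  masked <- mask_context(cands, corp)
  expect_equal(masked$context, "Aspirin causes pain today.")
})

test_that("every occurrence of a masked concept is replaced", {
  corp <- fixture_corpus(
    "Wide study.", "Aspirin links pain and pain but nausea stayed.",
    tibble::tibble(text = c("Aspirin", "pain", "nausea"),
                   etype = c("chemical", "disease", "disease"),
                   concept_id = c("C1", "D1", "D2"))) |> split_sentences()
  cands <- extract_candidates(corp)
  m2 <- mask_context(cands[cands$tail_id == "D2", ], corp)
  expect_false(grepl("pain", m2$context))
  expect_equal(lengths(regmatches(m2$context, gregexpr("UNK", m2$context))), 2L)
})

test_that("hypernym filtering removes ancestors of co-mentioned concepts", {
  corp <- fixture_corpus(
    "Aspirin effects.", "Aspirin causes pain. Aspirin causes headache.",
    tibble::tibble(text = c("Aspirin", "pain", "headache"),
                   etype = c("chemical", "disease", "disease"),
                   concept_id = c("C1", "Dpain", "Dhead"))) |> split_sentences()
  h <- krc_hierarchy(tibble::tibble(parent = "Dpain", child = "Dhead"))
  cands <- extract_candidates(corp)
  kept <- filter_hypernyms(cands, h, corp)
  expect_false("Dpain" %in% kept$tail_id)
  expect_true("Dhead" %in% kept$tail_id)
  # empty hierarchy removes nothing
  expect_equal(nrow(filter_hypernyms(cands, krc_hierarchy(), corp)),
               nrow(cands))
})

test_that("a hypernym without a more specific co-mention is kept", {
  corp <- fixture_corpus(
    "Aspirin note.", "Aspirin causes pain.",
    tibble::tibble(text = c("Aspirin", "pain"),
                   etype = c("chemical", "disease"),
                   concept_id = c("C1", "Dpain"))) |> split_sentences()
  h <- krc_hierarchy(tibble::tibble(parent = "Dpain", child = "Dhead"))
  cands <- filter_hypernyms(extract_candidates(corp), h, corp)
  expect_true("Dpain" %in% cands$tail_id)
})

test_that("filtering is monotone in the hierarchy", {
  syn <- small_synth(n_docs = 6, seed = 9)
  corp <- split_sentences(syn$corpus)
  cands <- extract_candidates(corp)
  dis <- sprintf("D%02d", 1:8)
  h_small <- krc_hierarchy(tibble::tibble(parent = dis[1], child = dis[2]))
  h_big <- krc_hierarchy(tibble::tibble(parent = dis[c(1, 1, 2)],
                                        child = dis[c(2, 3, 4)]))
  k_small <- filter_hypernyms(cands, h_small, corp)
  k_big <- filter_hypernyms(cands, h_big, corp)
  key <- function(d) paste(d$doc_id, d$head_id, d$tail_id)
  expect_true(all(key(k_big) %in% key(k_small)))
})

test_that("query construction follows the natural and pseudo templates", {
  expect_equal(build_query("flunitrazepan", "induce", "disease", "natural"),
               "what disease does flunitrazepan induce")
  expect_equal(build_query("flunitrazepan", "induce", "disease", "pseudo"),
               "flunitrazepan induce disease")
  expect_equal(build_query("aspirin", "react with", "chemical", "natural"),
               "what chemical does aspirin react with")
  expect_error(build_query("", "induce", "disease"), "empty")
  expect_error(build_query("x", "induce", "disease", "fancy"))
})

test_that("answers: earliest unmasked tail mention for positives, null else", {
  corp <- toy_doc()
  inst <- build_instances(corp)
  i_d1 <- inst[inst$tail_id == "D1", ]
  expect_equal(i_d1$label, "positive")
  # earliest headache mention in the title sentence context
  expect_equal(i_d1$answer_text, "headache")
  expect_equal(substr(i_d1$context, i_d1$answer_start + 1, i_d1$answer_end),
               "headache")
  i_d3 <- inst[inst$tail_id == "D3", ]
  expect_equal(i_d3$label, "negative")
  expect_true(is.na(i_d3$answer_start))
})

test_that("with two tail mentions in context the earliest is the answer", {
  corp <- fixture_corpus(
    "Pain focus.", "Aspirin causes pain and more pain daily.",
    tibble::tibble(text = c("Aspirin", "pain"),
                   etype = c("chemical", "disease"),
                   concept_id = c("C1", "D1")),
    gold = tibble::tibble(head_id = "C1", tail_id = "D1", relation = "CID")) |>
    split_sentences()
  inst <- build_instances(corp)
  first_pain <- regexpr("pain", inst$context, fixed = TRUE)
  expect_equal(inst$answer_start, as.integer(first_pain) - 1L)
})

test_that("no pair yields both levels and inter distances stay in bounds", {
  syn <- small_synth(n_docs = 10, seed = 21)
  cands <- extract_candidates(split_sentences(syn$corpus))
  key <- paste(cands$doc_id, cands$head_id, cands$tail_id)
  expect_equal(anyDuplicated(key), 0L)
  inter <- cands[cands$level == "inter", ]
  expect_true(all(inter$distance >= 1 & inter$distance <= 3))
})

test_that("positive instance count equals the generator's bookkeeping", {
  syn <- small_synth(n_docs = 10, seed = 13)
  inst <- build_instances(split_sentences(syn$corpus))
  expect_equal(sum(inst$label == "positive"),
               sum(syn$inventory$label == "positive"))
  # and the full inventory matches row for row
  got <- dplyr::arrange(inst[, c("doc_id", "head_id", "tail_id", "level", "label")],
                        doc_id, head_id, tail_id)
  want <- dplyr::arrange(syn$inventory[, c("doc_id", "head_id", "tail_id", "level", "label")],
                         doc_id, head_id, tail_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("instances serialize to SQuAD-v2-style JSON", {
  inst <- build_instances(toy_doc())
  f <- tempfile(fileext = ".json")
  write_squad(inst, f)
  j <- jsonlite::read_json(f)
  expect_equal(length(j$data), nrow(inst))
  imp <- vapply(j$data, function(x) x$is_impossible, logical(1))
  expect_equal(sum(!imp), sum(inst$label == "positive"))
  pos <- j$data[!imp][[1]]
  expect_equal(pos$answers[[1]]$text,
               inst$answer_text[inst$label == "positive"][1])
})
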