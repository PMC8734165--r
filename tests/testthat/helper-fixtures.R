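# Hand-built fixture corpora. Mention offsets are derived from the surface
# strings so the fixtures stay readable.

# annotate every occurrence of each surface form
annotate_all <- function(doc_id, text, surfaces) {
  purrr::map_dfr(seq_len(nrow(surfaces)), function(i) {
    s <- surfaces[i, ]
    m <- gregexpr(s$text, text, fixed = TRUE)[[1]]
    if (m[1] == -1) stop("surface not found: ", s$text)
    tibble::tibble(doc_id = doc_id, start = as.integer(m) - 1L,
                   end = as.integer(m) - 1L + nchar(s$text), text = s$text,
                   etype = s$etype, concept_id = s$concept_id)
  })
}

fixture_corpus <- function(title, abstract, surfaces, gold = NULL,
                           doc_id = "d1") {
  text <- paste0(title, "\n", abstract)
  men <- annotate_all(doc_id, text, surfaces)
  if (!is.null(gold)) gold$doc_id <- doc_id
  krc_corpus(tibble::tibble(doc_id = doc_id, title = title,
                            abstract = abstract),
             men, gold)
}

# the toy aspirin document: (C1,D1) intra, (C1,D2) inter at distance 1,
# (C1,D3) inter at distance 3 (w.r.t. the abstract Aspirin mention)
toy_doc <- function() {
  fixture_corpus(
    title = "Aspirin and headache.",
    abstract = paste("Aspirin causes headache. Nausea was seen.",
                     "Patients improved. Dizziness occurred later."),
    surfaces = tibble::tribble(
      ~text,       ~etype,     ~concept_id,
      "Aspirin",   "chemical", "C1",
      "headache",  "disease",  "D1",
      "Nausea",    "disease",  "D2",
      "Dizziness", "disease",  "D3"),
    gold = tibble::tibble(head_id = "C1", tail_id = c("D1", "D2"),
                          relation = "CID")) |>
    split_sentences()
}

# variant pushing Dizziness to sentence distance 4 from every Aspirin mention
toy_doc_far <- function() {
  fixture_corpus(
    title = "Analysis of headache.",
    abstract = paste("Aspirin causes headache. Nausea was seen.",
                     "Patients improved. Vitals were stable.",
                     "Dizziness occurred later."),
    surfaces = tibble::tribble(
      ~text,       ~etype,     ~concept_id,
      "Aspirin",   "chemical", "C1",
      "headache",  "disease",  "D1",
      "Nausea",    "disease",  "D2",
      "Dizziness", "disease",  "D3")) |>
    split_sentences()
}

small_synth <- function(n_docs = 5, seed = 11, ...) {
  gen_corpus(synth_config(n_docs = n_docs, seed = seed, ...))
}
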