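Package: krc
Title: Knowledge-Enhanced Reading Comprehension for Biomedical Relation Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Document-level biomedical relation extraction cast as span-extraction
    reading comprehension. Converts corpora of titles and abstracts with
    offset-anchored, concept-identified entity mentions (PubTator format) into
    question-answering instances at the intra- and inter-sentential level,
    learns translation-based (TransE) embeddings of knowledge-base relation
    triples, fuses them into a transformer encoder through a two-step bilinear
    attention mechanism, and decodes answer spans (with a null-answer
    convention for unexpressed relations) back into document-level entity-pair
    predictions scored by precision, recall and F1. Ships a seeded synthetic
    corpus, hierarchy and knowledge-base generator so the whole pipeline is
    testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
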