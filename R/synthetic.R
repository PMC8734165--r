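#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure of document-level chemical-disease
#' corpora at desk scale: multi-sentence title+abstract documents with typed,
#' concept-identified mentions; gold relation pairs expressed by an
#' unambiguous trigger verb either within one sentence or across sentences at
#' distance 1-3; a knowledge base whose labels overlap the corpus relation
#' plus noise; and a small concept tree with hypernym/hyponym co-occurrences.
#'
#' @param n_docs Number of documents.
#' @param n_chemicals,n_diseases Vocabulary sizes (IDs `C01...`, `D01...`).
#' @param sentences_per_abstract Minimum abstract length in sentences (filler
#'   sentences pad shorter abstracts).
#' @param p_positive_pair Probability that a candidate pair is a gold
#'   relation.
#' @param p_cooccur_same_sentence Probability that a pair is realized within
#'   one sentence (otherwise across sentences at distance 1-3).
#' @param kb_coverage Fraction of gold pairs present in the knowledge base
#'   with the task-positive label.
#' @param kb_noise Fraction of those knowledge-base entries whose label is
#'   corrupted to a conflicting one.
#' @param hierarchy_depth Depth of the generated disease concept tree
#'   (0 = empty).
#' @param seed Seed fixing all randomness.
#'
#' @return A list of class `krc_synth_config`.
#' @export
synth_config <- function(n_docs = 30L, n_chemicals = 6L, n_diseases = 8L,
                         sentences_per_abstract = 5L, p_positive_pair = 0.4,
                         p_cooccur_same_sentence = 0.6, kb_coverage = 1.0,
                         kb_noise = 0.0, hierarchy_depth = 2L, seed = 42L) {
  probs <- c(p_positive_pair, p_cooccur_same_sentence, kb_coverage, kb_noise)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(n_docs = as.integer(n_docs),
                 n_chemicals = as.integer(n_chemicals),
                 n_diseases = as.integer(n_diseases),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 p_positive_pair = p_positive_pair,
                 p_cooccur_same_sentence = p_cooccur_same_sentence,
                 kb_coverage = kb_coverage, kb_noise = kb_noise,
                 hierarchy_depth = as.integer(hierarchy_depth),
                 seed = as.integer(seed)),
            class = "krc_synth_config")
}

synth_chemical_names <- function(n) {
  stems <- c("amo", "bexa", "cori", "dala", "erlo", "folu", "gami", "hexo",
             "ixa", "jura", "kelo", "liro", "mavo", "nexi", "opra", "pazo")
  nm <- c(paste0(stems, "cillin"), paste0(stems, "zumab"))
  if (n > length(nm)) abort("chemical vocabulary exhausted")
  nm[seq_len(n)]
}

synth_disease_names <- function(n) {
  stems <- c("derma", "neuro", "cardio", "hepato", "nephro", "pulmo", "osteo",
             "gastro", "myo", "arthro", "angio", "entero", "kerato", "retino",
             "rhino", "cysto")
  nm <- c(paste0(stems, "pathy"), paste0(stems, "frenia"))
  if (n > length(nm)) abort("disease vocabulary exhausted")
  nm[seq_len(n)]
}

# sentence assembly: parts are plain strings or list(text=, id=, etype=)
mk_sentence <- function(...) {
  parts <- list(...)
  txt <- ""
  men <- list()
  for (p in parts) {
    if (is.character(p)) {
      txt <- paste0(txt, p)
    } else {
      men[[length(men) + 1L]] <- tibble(text = p$text, concept_id = p$id,
                                        etype = p$etype, rel_start = nchar(txt))
      txt <- paste0(txt, p$text)
    }
  }
  list(text = txt, mentions = if (length(men)) bind_rows(men) else
    tibble(text = character(), concept_id = character(), etype = character(),
           rel_start = integer()))
}

FILLERS <- c("Patients were monitored daily.", "Outcomes were recorded.",
             "Samples were collected weekly.", "Follow up continued.")

#' Generate a synthetic corpus with known ground truth
#'
#' Each document has a title naming one chemical and an abstract in which
#' every (chemical, disease) pair of the document is realized: gold pairs via
#' the trigger verb *induce* in one sentence (`"<chem> induces severe
#' <disease> ."`) or split across sentences within distance 3; negative
#' pairs via neutral verbs at the same levels. Besides the corpus the
#' generator returns its bookkeeping -- the true sentence boundaries and the
#' complete expected candidate inventory -- which downstream modules are
#' tested against.
#'
#' @param config A [synth_config()].
#'
#' @return A list of class `krc_synth` with elements `corpus`
#'   (a [krc_corpus()] without sentence spans), `sentences` (true boundary
#'   tibble), `inventory` (expected candidates: `doc_id`, `head_id`,
#'   `tail_id`, `level`, `label`) and `config`.
#' @export
gen_corpus <- function(config) {
  stopifnot(inherits(config, "krc_synth_config"))
  chem_nm <- synth_chemical_names(config$n_chemicals)
  dis_nm <- synth_disease_names(config$n_diseases)
  chem_id <- sprintf("C%02d", seq_len(config$n_chemicals))
  dis_id <- sprintf("D%02d", seq_len(config$n_diseases))
  if (config$n_chemicals < 1 || config$n_diseases < 2) {
    abort("need at least 1 chemical and 2 diseases")
  }
  with_seed_(config$seed, {
    # the relation is a property of the concept pair (as in a pair-level
    # knowledge base): decide positivity once per vocabulary pair, so every
    # document realizing a pair expresses the same world-level fact
    world_pos <- matrix(runif(config$n_chemicals * config$n_diseases) <
                          config$p_positive_pair,
                        config$n_chemicals, config$n_diseases)
    docs <- list(); mens <- list(); golds <- list(); sents <- list(); inv <- list()
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("s%03d", d)
      pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1)
      nc <- pick1(1:min(2L, config$n_chemicals))
      nd <- pick1(2:min(3L, config$n_diseases))
      ci <- sort(sample(config$n_chemicals, nc))
      di <- sort(sample(config$n_diseases, nd))
      chem <- function(i) list(text = chem_nm[i], id = chem_id[i], etype = "chemical")
      dis <- function(i) list(text = dis_nm[i], id = dis_id[i], etype = "disease")
      title <- mk_sentence("Clinical review of ", chem(ci[1]), " therapy.")
      sent_list <- list()
      add_sent <- function(s) sent_list[[length(sent_list) + 1L]] <<- s
      gold_doc <- list()
      for (c_i in ci) for (d_i in di) {
        positive <- world_pos[c_i, d_i]
        intra <- runif(1) < config$p_cooccur_same_sentence
        if (positive) gold_doc[[length(gold_doc) + 1L]] <- c(chem_id[c_i], dis_id[d_i])
        if (intra) {
          add_sent(if (positive) {
            mk_sentence(chem(c_i), " induces severe ", dis(d_i), " in patients.")
          } else {
            mk_sentence(chem(c_i), " was measured alongside ", dis(d_i), " markers.")
          })
        } else {
          delta <- sample(1:3, 1)
          add_sent(if (positive) {
            mk_sentence("Treatment with ", chem(c_i), " was continued.")
          } else {
            mk_sentence("Levels of ", chem(c_i), " were checked.")
          })
          for (f in seq_len(delta - 1L)) add_sent(mk_sentence(sample(FILLERS, 1)))
          add_sent(if (positive) {
            mk_sentence("Subsequent ", dis(d_i), " was induced by the regimen.")
          } else {
            mk_sentence("The ", dis(d_i), " remained stable throughout.")
          })
        }
      }
      while (length(sent_list) < config$sentences_per_abstract) {
        add_sent(mk_sentence(sample(FILLERS, 1)))
      }
      # assemble text and absolute offsets; title is sentence 0
      title_txt <- title$text
      abs_off <- nchar(title_txt) + 1L
      sent_rows <- list(tibble(doc_id = doc_id, sent_index = 0L, start = 0L,
                               end = nchar(title_txt)))
      men_rows <- list()
      if (nrow(title$mentions)) {
        men_rows[[1]] <- mutate(title$mentions, doc_id = doc_id,
                                start = .data$rel_start, sent_index = 0L)
      }
      abstract_txt <- ""
      for (si in seq_along(sent_list)) {
        s <- sent_list[[si]]
        s_start <- abs_off + nchar(abstract_txt)
        if (nzchar(abstract_txt)) {
          abstract_txt <- paste0(abstract_txt, " ")
          s_start <- s_start + 1L
        }
        abstract_txt <- paste0(abstract_txt, s$text)
        sent_rows[[length(sent_rows) + 1L]] <-
          tibble(doc_id = doc_id, sent_index = si, start = s_start,
                 end = s_start + nchar(s$text))
        if (nrow(s$mentions)) {
          men_rows[[length(men_rows) + 1L]] <-
            mutate(s$mentions, doc_id = doc_id,
                   start = .data$rel_start + s_start, sent_index = si)
        }
      }
      m <- bind_rows(men_rows) %>%
        mutate(end = .data$start + nchar(.data$text)) %>%
        select("doc_id", "start", "end", "text", "etype", "concept_id",
               "sent_index") %>%
        arrange(.data$start)
      docs[[d]] <- tibble(doc_id = doc_id, title = title_txt,
                          abstract = abstract_txt)
      mens[[d]] <- m
      sents[[d]] <- bind_rows(sent_rows)
      if (length(gold_doc)) {
        gp <- distinct(tibble(
          doc_id = doc_id,
          head_id = vapply(gold_doc, `[`, character(1), 1),
          tail_id = vapply(gold_doc, `[`, character(1), 2),
          relation = "CID"))
        golds[[length(golds) + 1L]] <- gp
      }
      # expected candidate inventory from the generator's own bookkeeping
      inv[[d]] <- purrr::map_dfr(ci, function(c_i) purrr::map_dfr(di, function(d_i) {
        cs <- m$sent_index[m$concept_id == chem_id[c_i]]
        ds <- m$sent_index[m$concept_id == dis_id[d_i]]
        dmat <- abs(outer(cs, ds, "-"))
        dmin <- min(dmat)
        if (dmin > 3L) return(NULL)
        tibble(doc_id = doc_id, head_id = chem_id[c_i], tail_id = dis_id[d_i],
               level = if (dmin == 0L) "intra" else "inter",
               distance = dmin,
               label = if (any(vapply(gold_doc, function(g)
                 g[1] == chem_id[c_i] && g[2] == dis_id[d_i], logical(1))))
                 "positive" else "negative")
      }))
    }
    corpus <- krc_corpus(bind_rows(docs),
                         select(bind_rows(mens), -"sent_index"),
                         if (length(golds)) bind_rows(golds) else NULL)
    structure(list(corpus = corpus, sentences = bind_rows(sents),
                   inventory = bind_rows(inv), config = config),
              class = "krc_synth")
  })
}

#' @export
print.krc_synth <- function(x, ...) {
  cat(sprintf("<krc_synth> %d document(s), %d gold pair(s), %d expected candidate(s)\n",
              nrow(x$corpus$documents), nrow(x$corpus$gold_pairs),
              nrow(x$inventory)))
  invisible(x)
}

#' Generate a disease concept hierarchy with planted co-occurrences
#'
#' Builds a tree of the configured depth over the disease concept IDs: the
#' first `depth + 1` concepts form a root-to-leaf chain and all remaining
#' concepts attach to the root. The returned `planted` tibble records, from
#' the generator's bookkeeping, every document that mentions both an ancestor
#' and one of its descendants -- exactly the candidates hypernym filtering
#' must remove.
#'
#' @param synth A `krc_synth` from [gen_corpus()] (or any corpus plus config).
#' @param config A [synth_config()]; defaults to the one inside `synth`.
#'
#' @return List with `hierarchy` (a [krc_hierarchy()]) and `planted`
#'   (tibble `doc_id`, `hyper_id`, `hypo_id`).
#' @export
gen_hierarchy <- function(synth, config = synth$config) {
  concepts <- sprintf("D%02d", seq_len(config$n_diseases))
  depth <- config$hierarchy_depth
  if (depth == 0L || length(concepts) < 2L) {
    return(list(hierarchy = krc_hierarchy(), planted = tibble(
      doc_id = character(), hyper_id = character(), hypo_id = character())))
  }
  chain_len <- min(depth + 1L, length(concepts))
  edges <- tibble(parent = concepts[seq_len(chain_len - 1L)],
                  child = concepts[2:chain_len])
  rest <- setdiff(concepts, concepts[seq_len(chain_len)])
  if (length(rest)) {
    edges <- bind_rows(edges, tibble(parent = concepts[1], child = rest))
  }
  h <- krc_hierarchy(edges)
  planted <- tibble(doc_id = character(), hyper_id = character(),
                    hypo_id = character())
  men <- synth$corpus$mentions
  for (doc in unique(men$doc_id)) {
    present <- unique(men$concept_id[men$doc_id == doc & men$etype == "disease"])
    for (id in present) {
      anc <- intersect(hierarchy_ancestors(h, id), present)
      if (length(anc)) {
        planted <- bind_rows(planted, tibble(doc_id = doc, hyper_id = anc,
                                             hypo_id = id))
      }
    }
  }
  list(hierarchy = h, planted = distinct(planted))
}

#' Generate a synthetic knowledge base over the gold pairs
#'
#' A `kb_coverage` fraction of the distinct gold pairs receives the
#' task-positive label (`marker/mechanism`); a `kb_noise` fraction of those
#' entries has its label corrupted to the conflicting `therapeutic`; and
#' roughly 30% of the non-gold corpus pairs receive a non-positive label
#' (`inferred-association` or `therapeutic`). The ground-truth label table is
#' returned alongside the triples.
#'
#' @param synth A `krc_synth` from [gen_corpus()].
#' @param config A [synth_config()]; defaults to the one inside `synth`.
#'
#' @return List with `triples` (tibble `head_id`, `relation`, `tail_id`) and
#'   `truth` (per-pair table with `gold` and `noisy` flags).
#' @export
gen_kb <- function(synth, config = synth$config) {
  gold <- distinct(synth$corpus$gold_pairs[, c("head_id", "tail_id")])
  all_pairs <- distinct(synth$inventory[, c("head_id", "tail_id")])
  nongold <- anti_join(all_pairs, gold, by = c("head_id", "tail_id"))
  with_seed_(config$seed + 1L, {
    n_cov <- floor(config$kb_coverage * nrow(gold))
    cov_idx <- if (nrow(gold)) sample.int(nrow(gold))[seq_len(n_cov)] else integer(0)
    covered <- gold[sort(cov_idx), , drop = FALSE]
    lab <- rep("marker/mechanism", nrow(covered))
    n_noise <- floor(config$kb_noise * nrow(covered))
    noise_idx <- if (nrow(covered)) sample.int(nrow(covered))[seq_len(n_noise)] else integer(0)
    lab[noise_idx] <- "therapeutic"
    ng_n <- floor(0.3 * nrow(nongold))
    ng_idx <- if (nrow(nongold)) sample.int(nrow(nongold))[seq_len(ng_n)] else integer(0)
    ng <- nongold[sort(ng_idx), , drop = FALSE]
    ng_lab <- sample(c("inferred-association", "therapeutic"), nrow(ng),
                     replace = TRUE)
    triples <- bind_rows(
      if (nrow(covered)) tibble(head_id = covered$head_id, relation = lab,
                                tail_id = covered$tail_id),
      if (nrow(ng)) tibble(head_id = ng$head_id, relation = ng_lab,
                           tail_id = ng$tail_id))
    truth <- bind_rows(
      if (nrow(covered)) tibble(head_id = covered$head_id,
                                tail_id = covered$tail_id, label = lab,
                                gold = TRUE,
                                noisy = seq_len(nrow(covered)) %in% noise_idx),
      if (nrow(ng)) tibble(head_id = ng$head_id, tail_id = ng$tail_id,
                           label = ng_lab, gold = FALSE, noisy = FALSE))
    list(triples = triples, truth = truth)
  })
}

#' Write a synthetic benchmark to disk
#'
#' Emits the PubTator corpus, hierarchy TSV, triple TSV and a ground-truth
#' JSON manifest (gold pairs, expected candidate inventory, true sentence
#' boundaries).
#'
#' @param synth A `krc_synth` from [gen_corpus()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths written.
#' @export
export_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(corpus = file.path(dir, "corpus.pubtator"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             triples = file.path(dir, "triples.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_pubtator(synth$corpus, paths[["corpus"]])
  hg <- gen_hierarchy(synth)
  write_hierarchy(hg$hierarchy, paths[["hierarchy"]])
  kb <- gen_kb(synth)
  write_triples(kb$triples, paths[["triples"]])
  jsonlite::write_json(
    list(config = unclass(synth$config),
         gold_pairs = synth$corpus$gold_pairs,
         inventory = synth$inventory,
         sentences = synth$sentences),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
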