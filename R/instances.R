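#' Extract candidate entity pairs at the intra- and inter-sentential level
#'
#' For every ordered (head concept, tail concept) pair in a document: if two
#' mentions co-occur in one sentence the pair yields a single *intra* candidate
#' whose context is that sentence (the earliest such sentence); otherwise, if
#' the minimal sentence distance between a head and a tail mention is at most
#' `max_inter_distance`, it yields a single *inter* candidate whose context is
#' the contiguous sentence window spanning the closest mention pair; otherwise
#' no candidate. A pair never yields both an intra and an inter candidate.
#' Mentions with the unresolved concept ID `"-1"` are ignored for pairing.
#'
#' In `chr_mode` (chemical-reaction corpora) head and tail are both chemicals,
#' the context is the full title+abstract, and no distance cutoff applies.
#'
#' @param corpus A [krc_corpus()] with sentences populated (see
#'   [split_sentences()]).
#' @param max_inter_distance Maximal sentence distance for inter-sentential
#'   candidates (ignored in `chr_mode`).
#' @param head_type,tail_type Entity types of the head and tail concept.
#' @param chr_mode Chemical-chemical mode with full-document contexts.
#'
#' @return A tibble with one row per candidate: `doc_id`, `head_id`,
#'   `tail_id`, `level` (`"intra"`/`"inter"`), `distance`, `head_text`,
#'   `sent_lo`, `sent_hi`, `win_start`, `win_end` (document offsets of the
#'   context window).
#' @export
extract_candidates <- function(corpus, max_inter_distance = 3L,
                               head_type = "chemical", tail_type = "disease",
                               chr_mode = FALSE) {
  stopifnot(inherits(corpus, "krc_corpus"))
  if (chr_mode) tail_type <- head_type
  have_sent <- unique(corpus$sentences$doc_id)
  missing <- setdiff(corpus$documents$doc_id, have_sent)
  if (length(missing)) {
    abort(sprintf("document(s) without sentence spans (run split_sentences first): %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i, ]
    sent <- corpus$sentences %>% filter(.data$doc_id == d$doc_id) %>%
      arrange(.data$sent_index)
    m <- corpus$mentions %>%
      filter(.data$doc_id == d$doc_id, .data$concept_id != "-1") %>%
      mutate(sent_index = purrr::map_int(.data$start, function(s) {
        sent$sent_index[which(sent$start <= s & s < sent$end)][1]
      }))
    heads <- m %>% filter(.data$etype == head_type)
    tails <- m %>% filter(.data$etype == tail_type)
    if (!nrow(heads) || !nrow(tails)) return(NULL)
    pairs <- tidyr::expand_grid(head_id = unique(heads$concept_id),
                                tail_id = unique(tails$concept_id))
    if (chr_mode) pairs <- filter(pairs, .data$head_id != .data$tail_id)
    purrr::pmap_dfr(pairs, function(head_id, tail_id) {
      hm <- heads %>% filter(.data$concept_id == head_id) %>% arrange(.data$start)
      tm <- tails %>% filter(.data$concept_id == tail_id) %>% arrange(.data$start)
      combos <- tidyr::expand_grid(hi = seq_len(nrow(hm)), ti = seq_len(nrow(tm))) %>%
        mutate(hs = hm$start[.data$hi], ts = tm$start[.data$ti],
               he = hm$end[.data$hi], te = tm$end[.data$ti],
               dist = abs(hm$sent_index[.data$hi] - tm$sent_index[.data$ti])) %>%
        filter(.data$hs >= .data$te | .data$ts >= .data$he)  # overlapping spans can't pair
      if (!nrow(combos)) return(NULL)
      dmin <- min(combos$dist)
      if (dmin == 0L) {
        level <- "intra"
      } else if (chr_mode || dmin <= max_inter_distance) {
        level <- "inter"
      } else {
        return(NULL)
      }
      best <- combos %>% filter(.data$dist == dmin) %>%
        arrange(.data$hs, .data$ts) %>% slice(1)
      s_h <- hm$sent_index[best$hi]; s_t <- tm$sent_index[best$ti]
      sent_lo <- min(s_h, s_t); sent_hi <- max(s_h, s_t)
      if (chr_mode) {
        win_start <- 0L
        win_end <- nchar(d$text)
      } else {
        win_start <- sent$start[sent$sent_index == sent_lo]
        win_end <- sent$end[sent$sent_index == sent_hi]
      }
      tibble(doc_id = d$doc_id, head_id = head_id, tail_id = tail_id,
             level = level, distance = dmin, head_text = hm$text[best$hi],
             sent_lo = sent_lo, sent_hi = sent_hi,
             win_start = as.integer(win_start), win_end = as.integer(win_end))
    })
  })
}

#' Remove candidates whose entities are hypernyms of more specific entities
#'
#' Document-level annotation guidelines keep only the most specific concept of
#' a hierarchy branch, so a candidate is dropped when its head or tail concept
#' is a (transitive) ancestor of another same-type concept mentioned in the
#' same document.
#'
#' @param candidates Candidate tibble from [extract_candidates()].
#' @param hierarchy A [krc_hierarchy()].
#' @param corpus The corpus the candidates came from.
#'
#' @return The filtered candidate tibble.
#' @export
filter_hypernyms <- function(candidates, hierarchy, corpus) {
  stopifnot(inherits(hierarchy, "krc_hierarchy"), inherits(corpus, "krc_corpus"))
  if (!nrow(candidates) || !nrow(hierarchy$edges)) return(candidates)
  present <- corpus$mentions %>%
    filter(.data$concept_id != "-1") %>%
    distinct(.data$doc_id, .data$etype, .data$concept_id)
  is_hyper_in_doc <- function(doc, id) {
    same_type <- present %>%
      filter(.data$doc_id == doc,
             .data$etype == present$etype[present$doc_id == doc &
                                            present$concept_id == id][1])
    others <- setdiff(same_type$concept_id, id)
    any(vapply(others, function(o) id %in% hierarchy_ancestors(hierarchy, o),
               logical(1)))
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    !is_hyper_in_doc(candidates$doc_id[i], candidates$head_id[i]) &&
      !is_hyper_in_doc(candidates$doc_id[i], candidates$tail_id[i])
  }, logical(1))
  candidates[keep, ]
}

#' Mask competing tail-type mentions in candidate contexts
#'
#' Within each candidate's context window, every tail-type mention span whose
#' concept IDs include neither the candidate's tail (nor, for same-type tasks,
#' its head) is replaced by a fixed placeholder token. The returned tibble
#' gains a `context` column plus list-columns `offset_map` (unmasked context
#' runs mapped back to document offsets) and `ctx_mentions` (surviving mention
#' projections with both context and document offsets).
#'
#' @param candidates Candidate tibble from [extract_candidates()].
#' @param corpus The source corpus.
#' @param mask_token Placeholder string for masked mentions.
#' @param tail_type Entity type subject to masking.
#' @param mask Set to `FALSE` to keep contexts unmasked (the projections are
#'   still computed).
#'
#' @return The candidate tibble with `context`, `offset_map`, `ctx_mentions`.
#' @export
mask_context <- function(candidates, corpus, mask_token = "UNK",
                         tail_type = "disease", mask = TRUE) {
  stopifnot(inherits(corpus, "krc_corpus"))
  txt <- setNames(corpus$documents$text, corpus$documents$doc_id)
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    m <- corpus$mentions %>%
      filter(.data$doc_id == cand$doc_id,
             .data$start >= cand$win_start, .data$end <= cand$win_end)
    keep_ids <- c(cand$tail_id, cand$head_id)
    spans <- m %>% group_by(.data$start, .data$end) %>%
      summarise(masked = mask &&
                  all(.data$etype == tail_type) &&
                  !any(.data$concept_id %in% keep_ids),
                .groups = "drop") %>%
      arrange(.data$start)
    mask_spans <- spans %>% filter(.data$masked)
    win_txt <- substr(txt[cand$doc_id], cand$win_start + 1L, cand$win_end)
    # build masked context and the piecewise offset map
    pieces <- character(0)
    map <- list()
    cursor_doc <- cand$win_start  # document offset of next unconsumed char
    cursor_ctx <- 0L
    emit_keep <- function(from, to) {  # doc offsets, half-open
      if (to <= from) return(invisible())
      piece <- substr(txt[cand$doc_id], from + 1L, to)
      pieces[[length(pieces) + 1L]] <<- piece
      map[[length(map) + 1L]] <<- tibble(ctx_start = cursor_ctx,
                                         ctx_end = cursor_ctx + (to - from),
                                         doc_start = from, doc_end = to)
      cursor_ctx <<- cursor_ctx + (to - from)
    }
    if (nrow(mask_spans)) {
      for (j in seq_len(nrow(mask_spans))) {
        emit_keep(cursor_doc, mask_spans$start[j])
        pieces[[length(pieces) + 1L]] <- mask_token
        cursor_ctx <- cursor_ctx + nchar(mask_token)
        cursor_doc <- mask_spans$end[j]
      }
    }
    emit_keep(cursor_doc, cand$win_end)
    context <- paste(pieces, collapse = "")
    map <- bind_rows(map)
    # project unmasked mentions into context coordinates
    kept <- m %>% anti_join(mask_spans, by = c("start", "end"))
    ctx_mentions <- if (nrow(kept)) {
      purrr::map_dfr(seq_len(nrow(kept)), function(j) {
        seg <- map %>% filter(.data$doc_start <= kept$start[j],
                              .data$doc_end >= kept$end[j])
        if (!nrow(seg)) return(NULL)  # mention overlapping a masked span
        cs <- seg$ctx_start[1] + (kept$start[j] - seg$doc_start[1])
        tibble(concept_id = kept$concept_id[j], etype = kept$etype[j],
               text = kept$text[j], ctx_start = cs,
               ctx_end = cs + (kept$end[j] - kept$start[j]),
               doc_start = kept$start[j], doc_end = kept$end[j])
      })
    } else {
      tibble(concept_id = character(), etype = character(), text = character(),
             ctx_start = integer(), ctx_end = integer(),
             doc_start = integer(), doc_end = integer())
    }
    cand$context <- context
    cand$offset_map <- list(map)
    cand$ctx_mentions <- list(ctx_mentions)
    cand
  })
  out
}

#' Build the query string for a candidate
#'
#' The *natural* style fills a per-task template
#' (`"what <tail type> does <head mention> <relation description>"`); the
#' *pseudo* style is the plain space-joined concatenation of head mention,
#' relation description and tail type.
#'
#' @param head_text Surface text of the head entity mention.
#' @param relation_description Short verb-phrase description of the queried
#'   relation (e.g. `"induce"` for chemical-induced disease).
#' @param tail_type Entity type of the expected answer.
#' @param style `"natural"` or `"pseudo"`.
#'
#' @return The query string.
#' @export
build_query <- function(head_text, relation_description, tail_type,
                        style = c("natural", "pseudo")) {
  if (!nzchar(head_text)) abort("empty head mention text")
  style <- match.arg(style)
  switch(style,
         natural = sprintf("what %s does %s %s", tail_type, head_text,
                           relation_description),
         pseudo = paste(head_text, relation_description, tail_type))
}

#' Assign gold answer spans to candidates
#'
#' A candidate is *positive* when `(head_id, tail_id)` is a gold pair of its
#' document; its answer is the earliest unmasked context mention of the tail
#' concept. Negative candidates get the null answer (`NA` offsets), following
#' the unanswerable-question convention.
#'
#' @param candidates Candidate tibble after [mask_context()].
#' @param corpus The source corpus.
#'
#' @return The tibble with columns `label` (`"positive"`/`"negative"`),
#'   `answer_start`, `answer_end` (context offsets) and `answer_text`.
#' @export
assign_answer <- function(candidates, corpus) {
  stopifnot(inherits(corpus, "krc_corpus"))
  gold <- corpus$gold_pairs
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    pos <- any(gold$doc_id == cand$doc_id & gold$head_id == cand$head_id &
                 gold$tail_id == cand$tail_id)
    cand$label <- if (pos) "positive" else "negative"
    if (pos) {
      tm <- cand$ctx_mentions[[1]] %>%
        filter(.data$concept_id == cand$tail_id) %>% arrange(.data$ctx_start)
      if (!nrow(tm)) {
        abort(sprintf("positive candidate (%s, %s) in %s has no tail mention in context",
                      cand$head_id, cand$tail_id, cand$doc_id))
      }
      cand$answer_start <- tm$ctx_start[1]
      cand$answer_end <- tm$ctx_end[1]
      cand$answer_text <- tm$text[1]
    } else {
      cand$answer_start <- NA_integer_
      cand$answer_end <- NA_integer_
      cand$answer_text <- NA_character_
    }
    cand
  })
}

#' Build reading-comprehension instances from a corpus
#'
#' Convenience pipeline: [extract_candidates()], optional
#' [filter_hypernyms()], [mask_context()], [build_query()] and
#' [assign_answer()].
#'
#' @inheritParams extract_candidates
#' @inheritParams mask_context
#' @param hierarchy Optional [krc_hierarchy()] for hypernym filtering.
#' @param relation_description Relation verb phrase used in queries.
#' @param query_style `"natural"` or `"pseudo"`.
#'
#' @return Instance tibble (one row per candidate, with `query`, `context`,
#'   `label` and answer columns).
#' @export
build_instances <- function(corpus, hierarchy = NULL,
                            relation_description = "induce",
                            query_style = "natural",
                            max_inter_distance = 3L,
                            head_type = "chemical", tail_type = "disease",
                            chr_mode = FALSE, mask_token = "UNK", mask = TRUE) {
  cands <- extract_candidates(corpus, max_inter_distance = max_inter_distance,
                              head_type = head_type, tail_type = tail_type,
                              chr_mode = chr_mode)
  if (chr_mode) tail_type <- head_type
  if (!is.null(hierarchy)) cands <- filter_hypernyms(cands, hierarchy, corpus)
  if (!nrow(cands)) {
    return(tibble(doc_id = character(), head_id = character(),
                  tail_id = character(), level = character()))
  }
  cands <- mask_context(cands, corpus, mask_token = mask_token,
                        tail_type = tail_type, mask = mask)
  cands$query <- vapply(cands$head_text, build_query, character(1),
                        relation_description = relation_description,
                        tail_type = tail_type, style = query_style)
  assign_answer(cands, corpus)
}

#' Serialize instances as SQuAD-v2-style JSON
#'
#' Writes one JSON file per level (`intra`, `inter`) or a single file, with
#' the familiar fields `question`, `context`, `answers` (`text`,
#' `answer_start`) and `is_impossible`.
#'
#' @param instances Instance tibble from [build_instances()].
#' @param file Output path; with `split_by_level` the level name is inserted
#'   before the extension.
#' @param split_by_level Write separate intra/inter files.
#'
#' @return Invisibly, the path(s) written.
#' @export
write_squad <- function(instances, file, split_by_level = FALSE) {
  ser <- function(df, path) {
    items <- purrr::map(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      pos <- identical(r$label, "positive")
      list(
        id = sprintf("%s_%s_%s", r$doc_id, r$head_id, r$tail_id),
        question = r$query,
        context = r$context,
        answers = if (pos) {
          list(list(text = r$answer_text, answer_start = r$answer_start))
        } else list(),
        is_impossible = !pos)
    })
    jsonlite::write_json(list(version = "v2.0", data = items), path,
                         auto_unbox = TRUE, null = "list")
    path
  }
  if (split_by_level) {
    paths <- vapply(c("intra", "inter"), function(lv) {
      p <- sub("(\\.[^.]+)?$", paste0(".", lv, "\\1"), file)
      ser(instances[instances$level == lv, ], p)
    }, character(1))
    return(invisible(paths))
  }
  invisible(ser(instances, file))
}
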