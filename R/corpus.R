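#' Corpus container for title/abstract documents with entity annotations
#'
#' A `krc_corpus` bundles four tibbles describing a collection of PubMed-style
#' documents: `documents` (one row per document), `mentions` (offset-anchored
#' entity mentions carrying concept IDs), `gold_pairs` (document-level relation
#' annotations) and `sentences` (sentence spans, populated by
#' [split_sentences()]). All character offsets are 0-based half-open indices
#' into the document text, which is `title`, a single `"\n"` separator, and
#' `abstract` -- the continuous-offset convention used by PubTator exports of
#' the BioCreative V corpora.
#'
#' @param documents tibble with columns `doc_id`, `title`, `abstract`.
#' @param mentions tibble with columns `doc_id`, `start`, `end`, `text`,
#'   `etype` (`"chemical"` or `"disease"`), `concept_id`.
#' @param gold_pairs tibble with columns `doc_id`, `head_id`, `tail_id`,
#'   `relation`.
#' @param sentences tibble with columns `doc_id`, `sent_index`, `start`, `end`,
#'   or `NULL` before segmentation.
#'
#' @return A `krc_corpus` object.
#' @export
krc_corpus <- function(documents, mentions, gold_pairs = NULL, sentences = NULL) {
  documents <- as_tibble(documents)
  documents$text <- paste0(documents$title, "\n", documents$abstract)
  mentions <- as_tibble(mentions)
  if (is.null(gold_pairs)) {
    gold_pairs <- tibble(doc_id = character(), head_id = character(),
                         tail_id = character(), relation = character())
  }
  if (is.null(sentences)) {
    sentences <- tibble(doc_id = character(), sent_index = integer(),
                        start = integer(), end = integer())
  }
  x <- structure(
    list(documents = documents, mentions = as_tibble(mentions),
         gold_pairs = as_tibble(gold_pairs), sentences = as_tibble(sentences)),
    class = "krc_corpus")
  validate_corpus(x)
  x
}

validate_corpus <- function(x) {
  docs <- x$documents
  men <- x$mentions
  if (anyDuplicated(docs$doc_id)) abort("duplicate doc_id in corpus")
  bad_type <- setdiff(unique(men$etype), c("chemical", "disease"))
  if (length(bad_type)) {
    abort(paste0("unknown entity type(s): ", paste(bad_type, collapse = ", ")))
  }
  txt <- setNames(docs$text, docs$doc_id)
  if (nrow(men)) {
    if (!all(men$doc_id %in% docs$doc_id)) abort("mention references unknown doc_id")
    dtxt <- txt[men$doc_id]
    ok_range <- men$start >= 0 & men$start < men$end & men$end <= nchar(dtxt)
    if (!all(ok_range)) {
      i <- which(!ok_range)[1]
      abort(sprintf("mention offsets out of range in document %s: [%d,%d)",
                    men$doc_id[i], men$start[i], men$end[i]))
    }
    sub <- substr(dtxt, men$start + 1L, men$end)
    ok_txt <- sub == men$text
    if (!all(ok_txt)) {
      i <- which(!ok_txt)[1]
      abort(sprintf(
        "mention text mismatch in document %s at [%d,%d): annotated '%s', document has '%s'",
        men$doc_id[i], men$start[i], men$end[i], men$text[i], sub[i]))
    }
  }
  invisible(x)
}

#' @export
print.krc_corpus <- function(x, ...) {
  cat(sprintf("<krc_corpus> %d document(s), %d mention(s), %d gold pair(s), %d sentence span(s)\n",
              nrow(x$documents), nrow(x$mentions), nrow(x$gold_pairs), nrow(x$sentences)))
  invisible(x)
}

#' Read a PubTator-format corpus
#'
#' Parses blank-line separated blocks of the form `"<id>|t|<title>"`,
#' `"<id>|a|<abstract>"`, followed by tab-separated mention lines
#' (`id, start, end, text, type, concept_id`) and relation lines
#' (`id, relation, id1, id2`). Mention offsets are validated against the
#' document text; a mismatch is an error naming the document and line.
#' Mentions annotated with several pipe-joined concept IDs (composite
#' annotations, as in CDR) are expanded into one row per ID sharing the span.
#'
#' @param file Path to a PubTator file, or a connection.
#' @param text Optionally, the raw text as a single string or character vector
#'   of lines (overrides `file`).
#'
#' @return A [krc_corpus()].
#' @export
read_pubtator <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }
  docs <- list(); men <- list(); rel <- list()
  cur <- NULL
  flush_doc <- function() {
    if (!is.null(cur)) docs[[length(docs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln_no in seq_along(lines)) {
    ln <- lines[[ln_no]]
    if (!nzchar(trimws(ln))) { flush_doc(); next }
    tpart <- regmatches(ln, regexec("^([^\t|]+)\\|t\\|(.*)$", ln))[[1]]
    apart <- regmatches(ln, regexec("^([^\t|]+)\\|a\\|(.*)$", ln))[[1]]
    if (length(tpart) == 3) {
      flush_doc()
      cur <- list(doc_id = tpart[2], title = tpart[3], abstract = "")
      next
    }
    if (length(apart) == 3) {
      if (is.null(cur) || cur$doc_id != apart[2]) {
        abort(sprintf("abstract line without matching title at line %d", ln_no))
      }
      cur$abstract <- apart[3]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) == 6) {
      etype <- tolower(f[5])
      if (!etype %in% c("chemical", "disease")) {
        abort(sprintf("unknown entity type '%s' in document %s (line %d)", f[5], f[1], ln_no))
      }
      ids <- strsplit(f[6], "|", fixed = TRUE)[[1]]
      if (!length(ids)) ids <- f[6]
      for (id in ids) {
        men[[length(men) + 1L]] <- tibble(
          doc_id = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
          text = f[4], etype = etype, concept_id = id, line = ln_no)
      }
    } else if (length(f) == 4) {
      rel[[length(rel) + 1L]] <- tibble(
        doc_id = f[1], relation = f[2], head_id = f[3], tail_id = f[4])
    } else {
      abort(sprintf("malformed PubTator line %d: '%s'", ln_no, ln))
    }
  }
  flush_doc()
  documents <- dplyr::bind_rows(lapply(docs, as_tibble))
  if (!nrow(documents)) {
    documents <- tibble(doc_id = character(), title = character(), abstract = character())
  }
  mentions <- if (length(men)) bind_rows(men) else {
    tibble(doc_id = character(), start = integer(), end = integer(),
           text = character(), etype = character(), concept_id = character(),
           line = integer())
  }
  gold <- if (length(rel)) {
    bind_rows(rel) %>% select("doc_id", "head_id", "tail_id", "relation") %>% distinct()
  } else NULL
  corp <- tryCatch(
    krc_corpus(documents, select(mentions, -"line"), gold),
    error = function(e) {
      abort(paste0("PubTator validation failed: ", conditionMessage(e)))
    })
  corp
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]: `read_pubtator(text = write_pubtator(x))`
#' reproduces `x` field for field (sentence spans are not serialized).
#'
#' @param corpus A [krc_corpus()].
#' @param file Optional path; when `NULL` the text is returned invisibly is
#'   returned as a character scalar.
#'
#' @return The PubTator text (invisibly when `file` is given).
#' @export
write_pubtator <- function(corpus, file = NULL) {
  stopifnot(inherits(corpus, "krc_corpus"))
  blocks <- vapply(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i, ]
    m <- corpus$mentions %>% filter(.data$doc_id == d$doc_id) %>%
      arrange(.data$start, .data$end, .data$concept_id)
    g <- corpus$gold_pairs %>% filter(.data$doc_id == d$doc_id)
    out <- c(paste0(d$doc_id, "|t|", d$title),
             paste0(d$doc_id, "|a|", d$abstract))
    if (nrow(m)) {
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", m$doc_id, m$start, m$end,
                            m$text, ifelse(m$etype == "chemical", "Chemical", "Disease"),
                            m$concept_id))
    }
    if (nrow(g)) {
      out <- c(out, sprintf("%s\t%s\t%s\t%s", g$doc_id, g$relation, g$head_id, g$tail_id))
    }
    paste(out, collapse = "\n")
  }, character(1))
  txt <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Segment documents into sentences
#'
#' The title is always its own sentence. The abstract is split after a
#' sentence-terminator character (default `.!?`) followed by whitespace, with
#' an abbreviation guard list; a candidate boundary falling strictly inside an
#' entity mention is discarded, so no mention ever straddles a sentence span.
#' Degenerate text yields a single sentence.
#'
#' @param corpus A [krc_corpus()].
#' @param terminators Characters that may end a sentence.
#' @param abbreviations Tokens (including their trailing period) after which no
#'   split is made.
#'
#' @return The corpus with its `sentences` tibble populated (`doc_id`,
#'   `sent_index` 0-based, `start`, `end` -- 0-based half-open offsets into the
#'   document text).
#' @export
split_sentences <- function(corpus,
                            terminators = c(".", "!", "?"),
                            abbreviations = c("i.e.", "e.g.", "etc.", "vs.",
                                              "cf.", "Fig.", "et al.")) {
  stopifnot(inherits(corpus, "krc_corpus"))
  sent <- purrr::map_dfr(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i, ]
    if (!nzchar(d$title) || !nzchar(d$abstract)) {
      abort(sprintf("document %s has an empty title or abstract", d$doc_id))
    }
    m <- corpus$mentions %>% filter(.data$doc_id == d$doc_id)
    off <- nchar(d$title) + 1L  # abstract offset past title + "\n"
    spans <- rbind(
      c(0L, nchar(d$title)),
      abstract_spans(d$abstract, terminators, abbreviations) + off)
    # merge spans around any boundary that would cut a mention in two
    repeat {
      bad <- FALSE
      for (j in seq_len(nrow(spans))) {
        inside <- m$start < spans[j, 1] & m$end > spans[j, 1]
        if (any(inside) && j > 1) {
          spans[j - 1, 2] <- spans[j, 2]
          spans <- spans[-j, , drop = FALSE]
          bad <- TRUE
          break
        }
      }
      if (!bad) break
    }
    tibble(doc_id = d$doc_id, sent_index = seq_len(nrow(spans)) - 1L,
           start = as.integer(spans[, 1]), end = as.integer(spans[, 2]))
  })
  corpus$sentences <- sent
  # every mention must now live inside exactly one span
  if (nrow(corpus$mentions)) {
    chk <- corpus$mentions %>%
      left_join(sent, by = "doc_id", relationship = "many-to-many") %>%
      filter(.data$start.x >= .data$start.y, .data$end.x <= .data$end.y) %>%
      dplyr::count(.data$doc_id, .data$start.x, .data$end.x, .data$concept_id)
    n_distinct_mentions <- nrow(distinct(corpus$mentions,
                                         .data$doc_id, .data$start, .data$end,
                                         .data$concept_id))
    if (nrow(chk) != n_distinct_mentions || any(chk$n != 1L)) {
      abort("sentence segmentation left a mention outside a unique sentence span")
    }
  }
  corpus
}

# 0-based half-open sentence spans over one abstract string
abstract_spans <- function(txt, terminators, abbreviations) {
  n <- nchar(txt)
  chars <- strsplit(txt, "")[[1]]
  bounds <- integer(0)
  for (p in seq_len(n - 1L)) {
    if (chars[p] %in% terminators && grepl("^\\s$", chars[p + 1L])) {
      # guard: does an abbreviation end exactly at p?
      guarded <- any(vapply(abbreviations, function(ab) {
        la <- nchar(ab)
        p >= la && substr(txt, p - la + 1L, p) == ab
      }, logical(1)))
      if (!guarded) bounds <- c(bounds, p)  # split after char p (1-based)
    }
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  spans <- cbind(starts, ends)
  # trim leading whitespace of each sentence
  for (j in seq_len(nrow(spans))) {
    while (spans[j, 1] < spans[j, 2] &&
           grepl("^\\s$", substr(txt, spans[j, 1] + 1L, spans[j, 1] + 1L))) {
      spans[j, 1] <- spans[j, 1] + 1L
    }
  }
  spans[spans[, 1] < spans[, 2], , drop = FALSE]
}

#' Read or write a concept hierarchy as two-column TSV
#'
#' The file has one `parent_id<TAB>child_id` edge per line (MeSH-style
#' is-a edges, parent = broader concept).
#'
#' @param file Path to the TSV file.
#' @return For `read_hierarchy()`, a [krc_hierarchy()].
#' @export
read_hierarchy <- function(file) {
  if (length(readLines(file, warn = FALSE)) == 0) return(krc_hierarchy())
  df <- utils::read.delim(file, header = FALSE, col.names = c("parent", "child"),
                          colClasses = "character")
  krc_hierarchy(as_tibble(df))
}

#' @rdname read_hierarchy
#' @param hierarchy A [krc_hierarchy()].
#' @export
write_hierarchy <- function(hierarchy, file) {
  utils::write.table(hierarchy$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read or write knowledge-base triples as three-column TSV
#'
#' Each line is `head_id<TAB>relation<TAB>tail_id`.
#'
#' @param file Path to the TSV file.
#' @return For `read_triples()`, a tibble with columns `head_id`, `relation`,
#'   `tail_id`.
#' @export
read_triples <- function(file) {
  if (length(readLines(file, warn = FALSE)) == 0) {
    return(tibble(head_id = character(), relation = character(), tail_id = character()))
  }
  df <- utils::read.delim(file, header = FALSE,
                          col.names = c("head_id", "relation", "tail_id"),
                          colClasses = "character")
  as_tibble(df)
}

#' @rdname read_triples
#' @param triples A tibble of triples.
#' @export
write_triples <- function(triples, file) {
  utils::write.table(triples[, c("head_id", "relation", "tail_id")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
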