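#' Merge instance-level decisions into document-level pair predictions
#'
#' A pair is positive as soon as at least one of its instances (intra or
#' inter) was decided positive. One record per `(doc_id, head_id, tail_id)`
#' is returned; `provenance` lists the level(s) whose instances fired
#' (comma-joined), or `NA` for a negative pair.
#'
#' @param decisions Tibble from [krc_predict()] (columns `doc_id`, `head_id`,
#'   `tail_id`, `level`, `decision`).
#'
#' @return Tibble with one row per pair: `doc_id`, `head_id`, `tail_id`,
#'   `positive`, `provenance`.
#' @export
merge_predictions <- function(decisions) {
  decisions %>%
    group_by(.data$doc_id, .data$head_id, .data$tail_id) %>%
    summarise(
      positive = any(.data$decision),
      provenance = if (any(.data$decision)) {
        paste(sort(unique(.data$level[.data$decision])), collapse = ",")
      } else NA_character_,
      .groups = "drop") %>%
    arrange(.data$doc_id, .data$head_id, .data$tail_id)
}

#' Fallback heuristic for documents without candidate instances
#'
#' Preprocessing (distance cutoffs, hypernym filtering) can leave a document
#' with no candidate instance at all; for those documents every chemical
#' mentioned in the title is paired positively with every tail-type entity
#' mentioned in the abstract. Documents that produced at least one candidate
#' are untouched, and no pair is ever removed.
#'
#' @param merged Pair predictions from [merge_predictions()].
#' @param corpus The source corpus.
#' @param candidates The candidate/instance tibble that fed the model (used
#'   to determine which documents produced no candidates).
#' @param tail_type Entity type of the tail side.
#'
#' @return `merged` with fallback pairs appended (`provenance = "fallback"`).
#' @export
apply_fallback <- function(merged, corpus, candidates, tail_type = "disease") {
  stopifnot(inherits(corpus, "krc_corpus"))
  no_cand <- setdiff(corpus$documents$doc_id, unique(candidates$doc_id))
  if (!length(no_cand)) return(merged)
  extra <- purrr::map_dfr(no_cand, function(doc) {
    d <- corpus$documents[corpus$documents$doc_id == doc, ]
    title_len <- nchar(d$title)
    m <- corpus$mentions %>%
      filter(.data$doc_id == doc, .data$concept_id != "-1")
    chems <- m %>% filter(.data$etype == "chemical", .data$end <= title_len)
    tails <- m %>% filter(.data$etype == tail_type, .data$start > title_len)
    if (!nrow(chems) || !nrow(tails)) return(NULL)
    tidyr::expand_grid(head_id = unique(chems$concept_id),
                       tail_id = unique(tails$concept_id)) %>%
      mutate(doc_id = doc, positive = TRUE, provenance = "fallback") %>%
      select("doc_id", "head_id", "tail_id", "positive", "provenance")
  })
  bind_rows(merged, extra) %>%
    distinct(.data$doc_id, .data$head_id, .data$tail_id, .keep_all = TRUE) %>%
    arrange(.data$doc_id, .data$head_id, .data$tail_id)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Evaluate pair predictions against gold annotations
#'
#' Document-level scoring compares the set of positively predicted
#' `(doc_id, head_id, tail_id)` pairs with the gold set. When a candidate
#' `level_map` is supplied, intra- and inter-sentential scores are added:
#' both predictions and gold pairs are restricted to pairs having at least
#' one candidate of that level. Precision is defined as 0 when there are no
#' positive predictions.
#'
#' @param predictions Pair predictions ([merge_predictions()] /
#'   [apply_fallback()] output; rows with `positive = FALSE` are ignored).
#' @param gold_pairs Tibble of gold pairs (`doc_id`, `head_id`, `tail_id`);
#'   duplicates are collapsed with a warning.
#' @param level_map Optional tibble (`doc_id`, `head_id`, `tail_id`, `level`)
#'   assigning candidate levels, e.g. the candidate tibble itself.
#'
#' @return A tibble of class `krc_eval`: one row per level (`document`, and
#'   `intra`/`inter` when `level_map` is given) with counts `tp`, `fp`, `fn`
#'   and `precision`, `recall`, `f1`.
#' @export
evaluate_pairs <- function(predictions, gold_pairs, level_map = NULL) {
  key <- function(df) paste(df$doc_id, df$head_id, df$tail_id, sep = "\r")
  gold <- as_tibble(gold_pairs)[, c("doc_id", "head_id", "tail_id")]
  if (anyDuplicated(key(gold))) {
    warn("duplicate gold pairs collapsed")
    gold <- distinct(gold)
  }
  pos <- predictions %>% filter(.data$positive) %>%
    distinct(.data$doc_id, .data$head_id, .data$tail_id)
  score <- function(pred_keys, gold_keys, level) {
    tp <- sum(pred_keys %in% gold_keys)
    fp <- length(pred_keys) - tp
    fn <- length(gold_keys) - tp
    m <- prf(tp, fp, fn)
    tibble(level = level, tp = tp, fp = fp, fn = fn,
           precision = m[["precision"]], recall = m[["recall"]], f1 = m[["f1"]])
  }
  out <- score(key(pos), key(gold), "document")
  if (!is.null(level_map)) {
    lm <- as_tibble(level_map)[, c("doc_id", "head_id", "tail_id", "level")]
    for (lv in c("intra", "inter")) {
      lv_keys <- key(lm[lm$level == lv, ])
      out <- bind_rows(out, score(intersect(key(pos), lv_keys),
                                  intersect(key(gold), lv_keys), lv))
    }
  }
  class(out) <- c("krc_eval", class(out))
  out
}

#' @export
tidy.krc_eval <- function(x, ...) as_tibble(unclass(x))

#' @export
autoplot.krc_eval <- function(object, ...) {
  df <- as_tibble(unclass(object)) %>%
    tidyr::pivot_longer(c("precision", "recall", "f1"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pair extraction performance")
}

#' Write or read pair predictions as TSV
#'
#' Columns: `doc_id`, `head_id`, `tail_id`, `level`, `decision`, `score`.
#'
#' @param predictions Prediction tibble.
#' @param file Path.
#' @return `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(file) {
  as_tibble(utils::read.delim(file, colClasses = NA))
}
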