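#' Training configuration
#'
#' Defaults mirror the reference setting for the chemical-induced disease
#' task: batch size 12 and learning rates 3e-5 (encoder) / 1e-4 (head); the
#' knowledge-enabled reference setting used 2e-5 / 3e-5, and chemical-reaction
#' corpora batch size 32. Runs with the tiny randomly initialized test encoder
#' train from scratch and use much larger rates (see the package vignette).
#'
#' @param batch_size Mini-batch size.
#' @param lr_encoder,lr_head Learning rates of the encoder and of the
#'   downstream attention/fusion/span-head parameter group.
#' @param epochs Number of passes over the instances.
#' @param seed RNG seed (shuffling is seeded; the whole run is deterministic).
#' @param warmup_frac Fraction of total steps with linearly warmed-up rates.
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param track_f1 Record document-level training F1 after each epoch.
#' @param max_answer_length,null_threshold Decoding parameters used when
#'   tracking F1 (see [decode_span()]).
#'
#' @return A list of class `krc_train_config`.
#' @export
krc_train_config <- function(batch_size = 12L, lr_encoder = 3e-5,
                             lr_head = 1e-4, epochs = 3L, seed = 1L,
                             warmup_frac = 0.1, weight_decay = 0.01,
                             track_f1 = FALSE, max_answer_length = 20L,
                             null_threshold = 0) {
  stopifnot(lr_encoder > 0, lr_head > 0)
  structure(list(batch_size = as.integer(batch_size), lr_encoder = lr_encoder,
                 lr_head = lr_head, epochs = as.integer(epochs),
                 seed = as.integer(seed), warmup_frac = warmup_frac,
                 weight_decay = weight_decay, track_f1 = track_f1,
                 max_answer_length = as.integer(max_answer_length),
                 null_threshold = null_threshold),
            class = "krc_train_config")
}

# map a character span in context coordinates to a token index range
char_span_to_tokens <- function(ct, cs, ce) {
  ts <- which(ct$end > cs & ct$start < ce)
  if (!length(ts)) return(NULL)
  range(ts)
}

# tokenize one instance and precompute its windows, gold packed indices and
# relation vectors
prep_instance <- function(inst, model, kb = NULL, stride = 32L) {
  enc <- model$encoder
  qt <- tokenize_text(inst$query)
  ct <- tokenize_text(inst$context)
  nq <- nrow(qt); nc <- nrow(ct)
  wins <- pack_windows(nq, nc, enc$spec$max_len, stride)
  gold_tok <- if (identical(inst$label, "positive")) {
    char_span_to_tokens(ct, inst$answer_start, inst$answer_end)
  } else NULL
  # window used for training: the one containing the gold span, else the first
  widx <- 1L
  if (!is.null(gold_tok)) {
    hit <- which(vapply(wins, function(w) all(gold_tok[1]:gold_tok[2] %in% w),
                        logical(1)))
    if (!length(hit)) abort("gold span not covered by any context window")
    widx <- hit[1]
  }
  relations <- if (model$use_kb) {
    if (is.null(kb)) abort("knowledge-enabled model needs a kb (triples + embeddings)")
    lookup_pair_relations(inst$head_id, inst$tail_id, kb$triples, kb$embeddings)
  } else {
    matrix(0, 1, model$d2)
  }
  qids <- vocab_lookup(enc$vocab, qt$token)
  cids <- vocab_lookup(enc$vocab, ct$token)
  cls <- enc$vocab[["[CLS]"]]; sep <- enc$vocab[["[SEP]"]]
  windows <- lapply(wins, function(w) {
    list(ids = c(cls, qids, sep, cids[w], sep),
         seg = c(rep(0L, nq + 2L), rep(1L, length(w) + 1L)),
         w = w, ctx_pos = seq_along(w) + nq + 2L)
  })
  train_w <- windows[[widx]]
  if (is.null(gold_tok)) {
    ys <- 1L; ye <- 1L
  } else {
    ys <- nq + 2L + match(gold_tok[1], train_w$w)
    ye <- nq + 2L + match(gold_tok[2], train_w$w)
  }
  list(ct = ct, windows = windows, train_w = train_w, ys = ys, ye = ye,
       relations = relations)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (is.matrix(params[[nm]])) weight_decay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(params = params, state = state)
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

#' Train a knowledge-enhanced reading-comprehension model
#'
#' Mini-batch gradient descent on the span cross-entropy loss with decoupled
#' weight decay, adaptive per-parameter step sizes and linear warmup. The
#' encoder and the downstream head form separate parameter groups with their
#' own learning rates. The run is deterministic under a fixed seed and single
#' thread.
#'
#' @param model A [krc_model()].
#' @param instances Instance tibble from [build_instances()].
#' @param corpus The source corpus (needed to resolve predictions when
#'   `track_f1` is on).
#' @param kb `NULL`, or a list with elements `triples` (the assembled triple
#'   store) and `embeddings` (a `krc_transe`), required when the model uses
#'   the knowledge path.
#' @param config A [krc_train_config()].
#'
#' @return A `krc_fit` with the trained `model`, per-epoch `loss`, per-epoch
#'   document-level `f1` (when tracked) and the `config`.
#' @export
krc_train <- function(model, instances, corpus = NULL, kb = NULL,
                      config = krc_train_config()) {
  if (!nrow(instances)) abort("empty instance set")
  preps <- lapply(seq_len(nrow(instances)),
                  function(i) prep_instance(instances[i, ], model, kb))
  n <- length(preps)
  enc_p <- model$encoder$params
  head_p <- model$head
  enc_state <- adamw_init(enc_p)
  head_state <- adamw_init(head_p)
  total_steps <- config$epochs * ceiling(n / config$batch_size)
  warm <- max(1, floor(config$warmup_frac * total_steps))
  loss_curve <- numeric(config$epochs)
  f1_curve <- rep(NA_real_, config$epochs)
  step <- 0L
  with_seed_(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bs in seq(1, n, by = config$batch_size)) {
        idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
        genc <- NULL; ghead <- NULL
        bloss <- 0
        for (i in idx) {
          pr <- preps[[i]]
          model$encoder$params <- enc_p
          fwd <- encoder_forward(model$encoder, pr$train_w$ids, pr$train_w$seg)
          hc <- head_forward(fwd$hidden, pr$relations, head_p,
                             use_kb = model$use_kb, kb_mode = model$kb_mode)
          bloss <- bloss + span_loss(hc$p_start, hc$p_end, pr$ys, pr$ye)
          hb <- head_backward(hc, head_p, pr$ys, pr$ye)
          ghead <- acc_grads(ghead, hb$grads)
          genc <- acc_grads(genc, encoder_backward(model$encoder, fwd$cache,
                                                   hb$dhidden))
        }
        m <- length(idx)
        genc <- lapply(genc, function(g) g / m)
        ghead <- lapply(ghead, function(g) g / m)
        ep_loss <- ep_loss + bloss
        step <- step + 1L
        lr_scale <- min(1, step / warm)
        up <- adamw_step(enc_p, genc, enc_state,
                         config$lr_encoder * lr_scale, config$weight_decay)
        enc_p <- up$params; enc_state <- up$state
        up <- adamw_step(head_p, ghead, head_state,
                         config$lr_head * lr_scale, config$weight_decay)
        head_p <- up$params; head_state <- up$state
      }
      loss_curve[ep] <- ep_loss / n
      if (isTRUE(config$track_f1)) {
        model$encoder$params <- enc_p
        model$head <- head_p
        dec <- predict_prepared(model, instances, preps,
                                max_answer_length = config$max_answer_length,
                                null_threshold = config$null_threshold,
                                corpus = corpus)
        merged <- merge_predictions(dec)
        merged <- apply_fallback(merged, corpus, instances)
        ev <- evaluate_pairs(merged, corpus$gold_pairs)
        f1_curve[ep] <- ev$f1[ev$level == "document"]
      }
    }
  })
  model$encoder$params <- enc_p
  model$head <- head_p
  structure(list(model = model, loss = loss_curve, f1 = f1_curve,
                 config = config, n_instances = n),
            class = "krc_fit")
}

#' @export
print.krc_fit <- function(x, ...) {
  cat(sprintf("<krc_fit> %d instance(s), %d epoch(s), final loss %.4f%s\n",
              x$n_instances, length(x$loss), x$loss[length(x$loss)],
              if (!all(is.na(x$f1)))
                sprintf(", final train F1 %.3f", x$f1[length(x$f1)]) else ""))
  invisible(x)
}

#' @export
tidy.krc_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), loss = x$loss, f1 = x$f1)
}

#' @export
glance.krc_fit <- function(x, ...) {
  tibble(epochs = length(x$loss), final_loss = x$loss[length(x$loss)],
         final_f1 = x$f1[length(x$f1)], n_instances = x$n_instances)
}

#' @export
autoplot.krc_fit <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("loss", "f1"), names_to = "metric") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training curves")
}

#' Decode the best answer span from start/end distributions
#'
#' Exhaustive argmax of `p_start[i] * p_end[j]` over context positions with
#' `i <= j < i + max_answer_length`, compared against the null score
#' `p_start[1] * p_end[1]` (position 1 is the `[CLS]` sentinel): the answer is
#' null when `null_score + null_threshold >= best_score`. Ties are broken by
#' the earlier start, then the shorter span.
#'
#' @param p_start,p_end Probability vectors over the packed positions.
#' @param context_positions 1-based positions eligible as answer tokens.
#' @param max_answer_length Maximal answer length in tokens.
#' @param null_threshold Additive bias towards the null answer.
#'
#' @return List with `start`, `end` (packed positions, `NA` when null),
#'   `score`, `null_score` and `is_null`.
#' @export
decode_span <- function(p_start, p_end, context_positions,
                        max_answer_length = 20L, null_threshold = 0) {
  cp <- sort(context_positions)
  best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
  for (i in cp) {
    js <- cp[cp >= i & cp < i + max_answer_length]
    if (!length(js)) next
    sc <- p_start[i] * p_end[js]
    jbest <- which.max(sc)
    if (sc[jbest] > best) {
      best <- sc[jbest]; bi <- i; bj <- js[jbest]
    }
  }
  null_score <- p_start[1] * p_end[1]
  if (!is.finite(best) || null_score + null_threshold >= best) {
    return(list(start = NA_integer_, end = NA_integer_, score = best,
                null_score = null_score, is_null = TRUE))
  }
  list(start = bi, end = bj, score = best, null_score = null_score,
       is_null = FALSE)
}

#' Resolve a decoded span to a document-level pair decision
#'
#' A candidate pair is predicted positive when the decoded span is non-null,
#' maps back cleanly to an unmasked region of the document, and its
#' case-insensitively normalized text equals the surface text of some mention
#' of the candidate's tail concept in the document.
#'
#' @param span A list as returned by [decode_span()], augmented with the
#'   context character offsets `ctx_start`, `ctx_end` (or `is_null = TRUE`).
#' @param candidate One row of the instance tibble (with `context`,
#'   `offset_map` and `tail_id`).
#' @param corpus The source corpus (supplies the tail concept's mention
#'   surface forms).
#'
#' @return Logical: positive decision.
#' @export
resolve_prediction <- function(span, candidate, corpus) {
  if (isTRUE(span$is_null)) return(FALSE)
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  map <- candidate$offset_map[[1]]
  covered <- any(map$ctx_start <= span$ctx_start & map$ctx_end >= span$ctx_end)
  if (!covered) return(FALSE)  # span touches a masked region
  txt <- substr(candidate$context, span$ctx_start + 1L, span$ctx_end)
  tails <- corpus$mentions %>%
    filter(.data$doc_id == candidate$doc_id,
           .data$concept_id == candidate$tail_id)
  any(norm(txt) == norm(tails$text))
}

# decode + resolve for prepared instances; all windows are scored and the
# best-scoring window wins
predict_prepared <- function(model, instances, preps, max_answer_length = 20L,
                             null_threshold = 0, corpus = NULL) {
  purrr::map_dfr(seq_along(preps), function(i) {
    inst <- instances[i, ]
    pr <- preps[[i]]
    best <- NULL
    for (wnd in pr$windows) {
      fwd <- encoder_forward(model$encoder, wnd$ids, wnd$seg)
      hc <- head_forward(fwd$hidden, pr$relations, model$head,
                         use_kb = model$use_kb, kb_mode = model$kb_mode)
      dec <- decode_span(hc$p_start, hc$p_end, wnd$ctx_pos,
                         max_answer_length, null_threshold)
      dec$wnd <- wnd
      if (is.null(best) || dec$score > best$score) best <- dec
    }
    span_text <- NA_character_
    positive <- FALSE
    if (!best$is_null) {
      wnd <- best$wnd
      ti <- wnd$w[best$start - (wnd$ctx_pos[1] - 1L)]
      tj <- wnd$w[best$end - (wnd$ctx_pos[1] - 1L)]
      best$ctx_start <- pr$ct$start[ti]
      best$ctx_end <- pr$ct$end[tj]
      span_text <- substr(inst$context, best$ctx_start + 1L, best$ctx_end)
      positive <- resolve_prediction(best, inst, corpus)
    }
    tibble(doc_id = inst$doc_id, head_id = inst$head_id,
           tail_id = inst$tail_id, level = inst$level, decision = positive,
           score = best$score, span_text = span_text)
  })
}

#' Predict pair decisions for a set of instances
#'
#' Runs the model over every instance (scoring all context windows and
#' keeping the best), decodes the answer span with the null convention, and
#' resolves it to a positive/negative decision per candidate pair instance.
#'
#' @param model A trained [krc_model()] (or the `model` element of a
#'   `krc_fit`).
#' @param instances Instance tibble from [build_instances()].
#' @param corpus The source corpus.
#' @param kb Knowledge store (`list(triples, embeddings)`) for
#'   knowledge-enabled models.
#' @param max_answer_length,null_threshold Decoding parameters.
#'
#' @return Tibble with `doc_id`, `head_id`, `tail_id`, `level`, `decision`,
#'   `score`, `span_text`.
#' @export
krc_predict <- function(model, instances, corpus, kb = NULL,
                        max_answer_length = 20L, null_threshold = 0) {
  if (inherits(model, "krc_fit")) model <- model$model
  preps <- lapply(seq_len(nrow(instances)),
                  function(i) prep_instance(instances[i, ], model, kb))
  predict_prepared(model, instances, preps, max_answer_length,
                   null_threshold, corpus)
}
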