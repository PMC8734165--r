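#' Assemble knowledge triples from a knowledge base and corpus pairs
#'
#' Takes the union of the knowledge-base triples and, for every corpus
#' candidate pair with no knowledge-base entry, one triple carrying the
#' `null_label` relation (encoding "no knowledge-base evidence"). Duplicates
#' are removed. With the three CTD relation labels this yields the four-label
#' triple store used for knowledge representation learning.
#'
#' @param corpus_pairs Tibble with columns `head_id`, `tail_id` (candidate
#'   entity pairs observed in the corpus).
#' @param kb_triples Tibble with columns `head_id`, `relation`, `tail_id`.
#' @param null_label Relation label for corpus pairs absent from the base.
#'
#' @return A tibble of distinct triples (`head_id`, `relation`, `tail_id`).
#' @export
assemble_triples <- function(corpus_pairs, kb_triples,
                             null_label = "null") {
  kb <- distinct(as_tibble(kb_triples)[, c("head_id", "relation", "tail_id")])
  pairs <- distinct(as_tibble(corpus_pairs)[, c("head_id", "tail_id")])
  absent <- anti_join(pairs, kb, by = c("head_id", "tail_id"))
  nulls <- if (nrow(absent)) {
    mutate(absent, relation = null_label)[, c("head_id", "relation", "tail_id")]
  } else NULL
  distinct(bind_rows(kb, nulls))
}

#' Learn TransE embeddings from a triple store
#'
#' Translation-based knowledge-graph embedding: a triple `(h, r, t)` is scored
#' by the energy `||h + r - t||_2` and training minimizes the margin ranking
#' loss between true triples and negatives obtained by corrupting the head or
#' the tail uniformly at random (one negative per positive per epoch).
#' Entity and relation vectors are initialized from a standard normal
#' distribution; entity vectors are renormalized to unit L2 norm at the start
#' of every epoch. The run is deterministic given `seed`.
#'
#' @param triples Tibble of triples (`head_id`, `relation`, `tail_id`), e.g.
#'   from [assemble_triples()].
#' @param d2 Embedding dimension.
#' @param epochs Number of passes over the triple store.
#' @param margin Ranking margin.
#' @param learning_rate Step size for the stochastic gradient updates.
#' @param seed RNG seed.
#'
#' @return A `krc_transe` object with elements `entities` (matrix, one row per
#'   concept ID), `relations` (one row per relation label), `d2`, `loss`
#'   (per-epoch mean margin loss) and the training `triples`.
#' @export
train_transe <- function(triples, d2 = 256L, epochs = 1000L, margin = 1,
                         learning_rate = 0.01, seed = 1L) {
  triples <- distinct(as_tibble(triples)[, c("head_id", "relation", "tail_id")])
  if (!nrow(triples)) abort("empty triple set")
  ents <- sort(unique(c(triples$head_id, triples$tail_id)))
  rels <- sort(unique(triples$relation))
  hidx <- match(triples$head_id, ents)
  ridx <- match(triples$relation, rels)
  tidx <- match(triples$tail_id, ents)
  n <- nrow(triples); nE <- length(ents)
  with_seed_(seed, {
    ent <- matrix(rnorm(nE * d2), nE, d2, dimnames = list(ents, NULL))
    rel <- matrix(rnorm(length(rels) * d2), length(rels), d2,
                  dimnames = list(rels, NULL))
    loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ent <- ent / pmax(sqrt(rowSums(ent^2)), 1e-12)
      corrupt_head <- runif(n) < 0.5
      repl <- sample.int(nE, n, replace = TRUE)
      nh <- ifelse(corrupt_head, repl, hidx)
      nt <- ifelse(corrupt_head, tidx, repl)
      dpos <- ent[hidx, , drop = FALSE] + rel[ridx, , drop = FALSE] -
        ent[tidx, , drop = FALSE]
      dneg <- ent[nh, , drop = FALSE] + rel[ridx, , drop = FALSE] -
        ent[nt, , drop = FALSE]
      epos <- sqrt(rowSums(dpos^2))
      eneg <- sqrt(rowSums(dneg^2))
      viol <- margin + epos - eneg > 0
      loss[ep] <- mean(pmax(0, margin + epos - eneg))
      if (any(viol)) {
        upos <- dpos[viol, , drop = FALSE] / pmax(epos[viol], 1e-12)
        uneg <- dneg[viol, , drop = FALSE] / pmax(eneg[viol], 1e-12)
        gE <- rowsum(rbind(upos, -upos, -uneg, uneg),
                     group = c(hidx[viol], tidx[viol], nh[viol], nt[viol]))
        gi <- as.integer(rownames(gE))
        ent[gi, ] <- ent[gi, ] - learning_rate * gE
        gR <- rowsum(upos - uneg, group = ridx[viol])
        ri <- as.integer(rownames(gR))
        rel[ri, ] <- rel[ri, ] - learning_rate * gR
      }
    }
    structure(list(entities = ent, relations = rel, d2 = as.integer(d2),
                   margin = margin, loss = loss, triples = triples),
              class = "krc_transe")
  })
}

#' @export
print.krc_transe <- function(x, ...) {
  cat(sprintf("<krc_transe> %d entities, %d relations, d2 = %d, %d epoch(s), final loss %.4f\n",
              nrow(x$entities), nrow(x$relations), x$d2, length(x$loss),
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Translation energy of triples under trained embeddings
#'
#' @param embeddings A `krc_transe` object.
#' @param head_id,relation,tail_id Vectors naming the triples to score.
#' @return Numeric vector of energies `||h + r - t||_2`.
#' @export
transe_energy <- function(embeddings, head_id, relation, tail_id) {
  stopifnot(inherits(embeddings, "krc_transe"))
  h <- embeddings$entities[head_id, , drop = FALSE]
  r <- embeddings$relations[relation, , drop = FALSE]
  t <- embeddings$entities[tail_id, , drop = FALSE]
  unname(sqrt(rowSums((h + r - t)^2)))
}

#' Rank-based tail prediction accuracy (hits at 1)
#'
#' For every triple, all known entities are ranked as candidate tails by
#' energy; the score is the fraction of triples whose true tail ranks first
#' (ties counted against the model).
#'
#' @param embeddings A `krc_transe` object.
#' @param triples Tibble of evaluation triples.
#' @return Fraction in `[0, 1]`.
#' @export
transe_hits_at_1 <- function(embeddings, triples) {
  stopifnot(inherits(embeddings, "krc_transe"))
  ent <- embeddings$entities
  hits <- vapply(seq_len(nrow(triples)), function(i) {
    hr <- ent[triples$head_id[i], ] + embeddings$relations[triples$relation[i], ]
    en <- sqrt(rowSums(sweep(ent, 2, hr, "-")^2))
    true_e <- en[triples$tail_id[i]]
    sum(en < true_e) == 0 && sum(en == true_e) == 1
  }, logical(1))
  mean(hits)
}

#' Candidate relation vectors for an entity pair
#'
#' Returns the embedding vectors of all non-null relation labels linking the
#' pair in the triple store, ordered lexicographically by label; when the pair
#' has no (non-null) entry, the single null-relation vector is returned, so
#' the result is never empty.
#'
#' @param head_id,tail_id Concept IDs of the pair.
#' @param triples Triple store tibble (see [assemble_triples()]).
#' @param embeddings A `krc_transe` trained on those triples.
#' @param null_label The null relation label.
#'
#' @return Matrix with one row per relation vector (`labels` as rownames).
#' @export
lookup_pair_relations <- function(head_id, tail_id, triples, embeddings,
                                  null_label = "null") {
  stopifnot(inherits(embeddings, "krc_transe"))
  labs <- sort(unique(triples$relation[triples$head_id == head_id &
                                         triples$tail_id == tail_id]))
  labs <- setdiff(labs, null_label)
  if (!length(labs)) labs <- null_label
  unknown <- setdiff(labs, rownames(embeddings$relations))
  if (length(unknown)) {
    abort(paste0("relation label(s) without embedding: ",
                 paste(unknown, collapse = ", ")))
  }
  embeddings$relations[labs, , drop = FALSE]
}

#' @export
tidy.krc_transe <- function(x, ...) {
  bind_rows(
    tibble(type = "entity", name = rownames(x$entities),
           vector = purrr::map(seq_len(nrow(x$entities)), ~ x$entities[.x, ])),
    tibble(type = "relation", name = rownames(x$relations),
           vector = purrr::map(seq_len(nrow(x$relations)), ~ x$relations[.x, ])))
}

#' @export
glance.krc_transe <- function(x, ...) {
  tibble(n_entities = nrow(x$entities), n_relations = nrow(x$relations),
         d2 = x$d2, epochs = length(x$loss), final_loss = x$loss[length(x$loss)])
}

#' @export
autoplot.krc_transe <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean margin loss",
                  title = "TransE training loss")
}

#' Write / read a TransE embedding store as TSV
#'
#' Portable plain-text serialization: one row per vector, first columns `type`
#' (`entity`/`relation`) and `name`, then the `d2` coordinates.
#'
#' @param embeddings A `krc_transe` object.
#' @param file Path.
#' @return `read_transe()` returns a `krc_transe` (without loss history).
#' @export
write_transe <- function(embeddings, file) {
  df <- rbind(
    data.frame(type = "entity", name = rownames(embeddings$entities),
               embeddings$entities, check.names = FALSE),
    data.frame(type = "relation", name = rownames(embeddings$relations),
               embeddings$relations, check.names = FALSE))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_transe
#' @export
read_transe <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  ent <- mat[df$type == "entity", , drop = FALSE]
  rownames(ent) <- df$name[df$type == "entity"]
  rel <- mat[df$type == "relation", , drop = FALSE]
  rownames(rel) <- df$name[df$type == "relation"]
  colnames(ent) <- colnames(rel) <- NULL
  structure(list(entities = ent, relations = rel, d2 = ncol(ent),
                 margin = NA_real_, loss = numeric(0),
                 triples = tibble(head_id = character(), relation = character(),
                                  tail_id = character())),
            class = "krc_transe")
}
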