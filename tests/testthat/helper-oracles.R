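# Independent per-position loop oracles for the attention equations and the
# span head, written directly from their scalar definitions.

oracle_select_attention <- function(hidden, relations, W1, b1) {
  k <- nrow(hidden); Tn <- nrow(relations); d2 <- ncol(relations)
  k_mat <- matrix(0, k, d2)
  alpha <- matrix(0, k, Tn)
  for (i in seq_len(k)) {
    logits <- numeric(Tn)
    for (t in seq_len(Tn)) {
      logits[t] <- drop(hidden[i, ] %*% W1 %*% relations[t, ]) + b1
    }
    a <- exp(logits) / sum(exp(logits))
    alpha[i, ] <- a
    for (t in seq_len(Tn)) k_mat[i, ] <- k_mat[i, ] + a[t] * relations[t, ]
  }
  list(k_mat = k_mat, alpha = alpha)
}

oracle_context_attention <- function(k_mat, hidden, W2, b2) {
  k <- nrow(hidden); d1 <- ncol(hidden)
  h_prime <- matrix(0, k, d1)
  beta <- matrix(0, k, k)
  for (i in seq_len(k)) {
    logits <- numeric(k)
    for (j in seq_len(k)) {
      logits[j] <- drop(k_mat[i, ] %*% W2 %*% hidden[j, ]) + b2
    }
    b <- exp(logits) / sum(exp(logits))
    beta[i, ] <- b
    for (j in seq_len(k)) h_prime[i, ] <- h_prime[i, ] + b[j] * hidden[j, ]
  }
  list(h_prime = h_prime, beta = beta)
}

oracle_fuse_predict <- function(hidden, h_prime, params, use_kb = TRUE) {
  k <- nrow(hidden)
  ffn <- function(u, W3, b3, W4, b4) {
    drop(pmax(drop(u %*% W3) + b3, 0) %*% W4) + b4
  }
  ls <- numeric(k); le <- numeric(k)
  for (i in seq_len(k)) {
    u_i <- if (use_kb) {
      v_i <- drop(hidden[i, ] %*% params$Wh) +
        drop(h_prime[i, ] %*% params$Whp) + params$b
      c(h_prime[i, ], v_i)
    } else {
      c(hidden[i, ], drop(hidden[i, ] %*% params$Wh) + params$b)
    }
    ls[i] <- ffn(matrix(u_i, 1), params$W3s, params$b3s, params$W4s, params$b4s)
    le[i] <- ffn(matrix(u_i, 1), params$W3e, params$b3e, params$W4e, params$b4e)
  }
  list(p_start = exp(ls) / sum(exp(ls)), p_end = exp(le) / sum(exp(le)))
}

# exhaustive decode oracle over all (i, j) pairs
oracle_decode <- function(p_start, p_end, context_positions,
                          max_answer_length, null_threshold = 0) {
  best <- -Inf; bi <- NA; bj <- NA
  for (i in context_positions) {
    for (j in context_positions) {
      if (j < i || j >= i + max_answer_length) next
      sc <- p_start[i] * p_end[j]
      better <- sc > best ||
        (sc == best && !is.na(bi) && (i < bi || (i == bi && j < bj)))
      if (better) { best <- sc; bi <- i; bj <- j }
    }
  }
  null_score <- p_start[1] * p_end[1]
  if (!is.finite(best) || null_score + null_threshold >= best) {
    list(start = NA_integer_, end = NA_integer_, is_null = TRUE)
  } else {
    list(start = bi, end = bj, is_null = FALSE)
  }
}

rand_case <- function(k, d1, d2, Tn) {
  list(hidden = matrix(rnorm(k * d1), k, d1),
       relations = matrix(rnorm(Tn * d2), Tn, d2),
       W1 = matrix(rnorm(d1 * d2), d1, d2),
       W2 = matrix(rnorm(d2 * d1), d2, d1))
}

# planted knowledge base: 20 entities, 3 relations; entities get latent
# positions and each (head, relation) pair's tail is the entity nearest to
# latent(head) + latent(relation), so the triples are translation-consistent
# by construction
planted_kb <- function(n_ent = 20L, n_rel = 3L, latent_dim = 4L, seed = 99L) {
  set.seed(seed)
  ents <- sprintf("e%02d", seq_len(n_ent))
  ze <- matrix(rnorm(n_ent * latent_dim), n_ent, latent_dim)
  ze <- ze / sqrt(rowSums(ze^2))
  zr <- matrix(rnorm(n_rel * latent_dim, sd = 0.5), n_rel, latent_dim)
  purrr::map_dfr(seq_len(n_rel), function(k) {
    tails <- vapply(seq_len(n_ent), function(i) {
      target <- ze[i, ] + zr[k, ]
      d <- sqrt(rowSums(sweep(ze, 2, target, "-")^2))
      d[i] <- Inf  # a self-loop tail would make the triple degenerate
      which.min(d)
    }, integer(1))
    tibble::tibble(head_id = ents, relation = paste0("r", k),
                   tail_id = ents[tails])
  })
}

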