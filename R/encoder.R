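#' Toy whitespace tokenizer with character offsets
#'
#' Splits on whitespace and separates punctuation characters into their own
#' tokens, keeping 0-based half-open character offsets so decoded token spans
#' can be mapped back to text. This removes subword alignment from desk-scale
#' experiments; any tokenizer honoring the same output contract (a tibble of
#' `token`, `start`, `end`) can be substituted.
#'
#' @param text A single string.
#' @return Tibble with columns `token`, `start`, `end`.
#' @export
tokenize_text <- function(text) {
  m <- gregexpr("[[:alnum:]_'-]+|[^[:alnum:]_'[:space:]-]", text)[[1]]
  if (m[1] == -1) return(tibble(token = character(), start = integer(), end = integer()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble(token = regmatches(text, list(m))[[1]],
         start = starts, end = starts + lens)
}

#' Build a vocabulary over a token stream
#'
#' @param tokens Character vector of tokens (case-folded internally).
#' @param specials Reserved tokens, prepended in order; `[UNK]` absorbs
#'   out-of-vocabulary tokens at lookup time.
#' @return Named integer vector mapping token to ID (1-based).
#' @export
build_vocab <- function(tokens, specials = c("[PAD]", "[CLS]", "[SEP]", "[UNK]")) {
  toks <- sort(unique(setdiff(tolower(tokens), specials)))
  setNames(seq_along(c(specials, toks)), c(specials, toks))
}

vocab_lookup <- function(vocab, tokens) {
  ids <- unname(vocab[tolower(tokens)])
  ids[is.na(ids)] <- vocab[["[UNK]"]]
  ids
}

#' Configuration of the tiny test transformer encoder
#'
#' A 2-layer, 2-head transformer with 32-dimensional hidden states and a
#' whitespace tokenizer, randomly initialized under a fixed seed. It honors
#' the same contract as a pretrained language-model encoder (one hidden vector
#' per packed token) and is sized so the whole pipeline trains on a CPU in
#' seconds-to-minutes.
#'
#' @param d1 Hidden size.
#' @param n_layers,n_heads Depth and head count.
#' @param d_ff Feed-forward inner width.
#' @param max_len Maximum packed sequence length (longer inputs are windowed).
#' @return A list of encoder hyperparameters.
#' @export
tiny_encoder_spec <- function(d1 = 32L, n_layers = 2L, n_heads = 2L,
                              d_ff = 64L, max_len = 128L) {
  stopifnot(d1 %% n_heads == 0)
  list(d1 = as.integer(d1), n_layers = as.integer(n_layers),
       n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
       max_len = as.integer(max_len))
}

#' Instantiate a randomly initialized encoder over a vocabulary
#'
#' @param spec Encoder hyperparameters from [tiny_encoder_spec()].
#' @param vocab Vocabulary from [build_vocab()].
#' @param seed RNG seed fixing the initialization.
#' @return A `krc_encoder` object (spec, vocab and a flat named parameter
#'   list).
#' @export
init_encoder <- function(spec, vocab, seed = 1L) {
  V <- length(vocab); d1 <- spec$d1; d_ff <- spec$d_ff
  with_seed_(seed, {
    p <- list(
      tok_emb = matrix(rnorm(V * d1, sd = 0.02), V, d1),
      pos_emb = matrix(rnorm(spec$max_len * d1, sd = 0.02), spec$max_len, d1),
      seg_emb = matrix(rnorm(2 * d1, sd = 0.02), 2, d1))
    for (l in seq_len(spec$n_layers)) {
      pre <- function(nm) paste0("L", l, ".", nm)
      p[[pre("Wq")]] <- matrix(rnorm(d1 * d1, sd = 0.02), d1, d1)
      p[[pre("Wk")]] <- matrix(rnorm(d1 * d1, sd = 0.02), d1, d1)
      p[[pre("Wv")]] <- matrix(rnorm(d1 * d1, sd = 0.02), d1, d1)
      p[[pre("Wo")]] <- matrix(rnorm(d1 * d1, sd = 0.02), d1, d1)
      p[[pre("bq")]] <- numeric(d1); p[[pre("bk")]] <- numeric(d1)
      p[[pre("bv")]] <- numeric(d1); p[[pre("bo")]] <- numeric(d1)
      p[[pre("ln1_g")]] <- rep(1, d1); p[[pre("ln1_b")]] <- numeric(d1)
      p[[pre("Wf1")]] <- matrix(rnorm(d1 * d_ff, sd = 0.02), d1, d_ff)
      p[[pre("bf1")]] <- numeric(d_ff)
      p[[pre("Wf2")]] <- matrix(rnorm(d_ff * d1, sd = 0.02), d_ff, d1)
      p[[pre("bf2")]] <- numeric(d1)
      p[[pre("ln2_g")]] <- rep(1, d1); p[[pre("ln2_b")]] <- numeric(d1)
    }
    structure(list(spec = spec, vocab = vocab, params = p),
              class = "krc_encoder")
  })
}

#' @export
print.krc_encoder <- function(x, ...) {
  cat(sprintf("<krc_encoder> %d layer(s), %d head(s), d1 = %d, |vocab| = %d\n",
              x$spec$n_layers, x$spec$n_heads, x$spec$d1, length(x$vocab)))
  invisible(x)
}

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)), xhat = xhat, inv = inv)
}

layernorm_backward <- function(cache, g, dy) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# forward through the transformer stack; returns hidden states and a cache
# sufficient for encoder_backward
encoder_forward <- function(encoder, ids, seg) {
  p <- encoder$params; sp <- encoder$spec
  k <- length(ids); d1 <- sp$d1; H <- sp$n_heads; dh <- d1 %/% H
  x <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(k), , drop = FALSE] +
    p$seg_emb[seg + 1L, , drop = FALSE]
  cache <- list(ids = ids, seg = seg, layers = vector("list", sp$n_layers))
  for (l in seq_len(sp$n_layers)) {
    pre <- function(nm) paste0("L", l, ".", nm)
    Q <- x %*% p[[pre("Wq")]] + rep(p[[pre("bq")]], each = k)
    K <- x %*% p[[pre("Wk")]] + rep(p[[pre("bk")]], each = k)
    V <- x %*% p[[pre("Wv")]] + rep(p[[pre("bv")]], each = k)
    O <- matrix(0, k, d1)
    A <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
      A[[h]] <- softmax_rows(S)
      O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    att <- O %*% p[[pre("Wo")]] + rep(p[[pre("bo")]], each = k)
    ln1 <- layernorm_forward(x + att, p[[pre("ln1_g")]], p[[pre("ln1_b")]])
    z1 <- ln1$y
    f_pre <- z1 %*% p[[pre("Wf1")]] + rep(p[[pre("bf1")]], each = k)
    f_act <- pmax(f_pre, 0)
    ff <- f_act %*% p[[pre("Wf2")]] + rep(p[[pre("bf2")]], each = k)
    ln2 <- layernorm_forward(z1 + ff, p[[pre("ln2_g")]], p[[pre("ln2_b")]])
    cache$layers[[l]] <- list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                              ln1 = ln1, z1 = z1, f_pre = f_pre, f_act = f_act,
                              ln2 = ln2)
    x <- ln2$y
  }
  list(hidden = x, cache = cache)
}

# backward through the transformer stack. dh_out: k x d1 gradient on the
# hidden states. Returns a flat named list of parameter gradients.
encoder_backward <- function(encoder, cache, dh_out) {
  p <- encoder$params; sp <- encoder$spec
  ids <- cache$ids; seg <- cache$seg
  k <- length(ids); d1 <- sp$d1; H <- sp$n_heads; dh <- d1 %/% H
  g <- list()
  dx <- dh_out
  for (l in rev(seq_len(sp$n_layers))) {
    pre <- function(nm) paste0("L", l, ".", nm)
    cc <- cache$layers[[l]]
    lb2 <- layernorm_backward(cc$ln2, p[[pre("ln2_g")]], dx)
    g[[pre("ln2_g")]] <- lb2$dg; g[[pre("ln2_b")]] <- lb2$db
    dsum2 <- lb2$dx                       # grad on z1 + ff
    # FFN branch
    g[[pre("Wf2")]] <- t(cc$f_act) %*% dsum2
    g[[pre("bf2")]] <- colSums(dsum2)
    df_act <- dsum2 %*% t(p[[pre("Wf2")]])
    df_pre <- df_act * (cc$f_pre > 0)
    g[[pre("Wf1")]] <- t(cc$z1) %*% df_pre
    g[[pre("bf1")]] <- colSums(df_pre)
    dz1 <- dsum2 + df_pre %*% t(p[[pre("Wf1")]])
    lb1 <- layernorm_backward(cc$ln1, p[[pre("ln1_g")]], dz1)
    g[[pre("ln1_g")]] <- lb1$dg; g[[pre("ln1_b")]] <- lb1$db
    dsum1 <- lb1$dx                       # grad on x + att
    # attention output projection
    g[[pre("Wo")]] <- t(cc$O) %*% dsum1
    g[[pre("bo")]] <- colSums(dsum1)
    dO <- dsum1 %*% t(p[[pre("Wo")]])
    dQ <- matrix(0, k, d1); dK <- matrix(0, k, d1); dV <- matrix(0, k, d1)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOh
      dS <- softmax_rows_backward(A, dA) / sqrt(dh)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE]
    }
    g[[pre("Wq")]] <- t(cc$x) %*% dQ; g[[pre("bq")]] <- colSums(dQ)
    g[[pre("Wk")]] <- t(cc$x) %*% dK; g[[pre("bk")]] <- colSums(dK)
    g[[pre("Wv")]] <- t(cc$x) %*% dV; g[[pre("bv")]] <- colSums(dV)
    dx <- dsum1 + dQ %*% t(p[[pre("Wq")]]) + dK %*% t(p[[pre("Wk")]]) +
      dV %*% t(p[[pre("Wv")]])
  }
  # embedding gradients
  ge <- rowsum(dx, group = ids)
  tok <- matrix(0, nrow(p$tok_emb), d1)
  tok[as.integer(rownames(ge)), ] <- ge
  g$tok_emb <- tok
  pos <- matrix(0, nrow(p$pos_emb), d1)
  pos[seq_len(k), ] <- dx
  g$pos_emb <- pos
  gs <- rowsum(dx, group = seg + 1L)
  segm <- matrix(0, 2, d1)
  segm[as.integer(rownames(gs)), ] <- gs
  g$seg_emb <- segm
  g
}

#' Pack and encode a query/context token pair
#'
#' Builds the packed sequence `[CLS] Q [SEP] C [SEP]` (segment 0 for the query
#' part, 1 for the context part) and runs the encoder. Sequences exceeding the
#' encoder's maximum length are split into overlapping context windows of the
#' given stride; each window is encoded independently.
#'
#' @param query_tokens,context_tokens Character vectors of tokens.
#' @param encoder A `krc_encoder` from [init_encoder()].
#' @param stride Context token overlap step used when windowing.
#'
#' @return A list of windows; each window is a list with `ids`, `seg`,
#'   `ctx_idx` (indices into `context_tokens` covered by the window),
#'   `ctx_pos` (their 1-based positions in the packed sequence) and `hidden`
#'   (the `k x d1` matrix of token vectors).
#' @export
encode <- function(query_tokens, context_tokens, encoder, stride = 32L) {
  stopifnot(inherits(encoder, "krc_encoder"))
  if (!length(context_tokens)) abort("empty context")
  windows <- pack_windows(length(query_tokens), length(context_tokens),
                          encoder$spec$max_len, stride)
  cls <- encoder$vocab[["[CLS]"]]; sep <- encoder$vocab[["[SEP]"]]
  qids <- vocab_lookup(encoder$vocab, query_tokens)
  cids <- vocab_lookup(encoder$vocab, context_tokens)
  lapply(windows, function(w) {
    ids <- c(cls, qids, sep, cids[w], sep)
    seg <- c(rep(0L, length(qids) + 2L), rep(1L, length(w) + 1L))
    out <- encoder_forward(encoder, ids, seg)
    list(ids = ids, seg = seg, ctx_idx = w,
         ctx_pos = seq_along(w) + length(qids) + 2L,
         hidden = out$hidden, cache = out$cache)
  })
}

# split n_ctx context tokens into windows fitting max_len alongside the query
pack_windows <- function(n_query, n_ctx, max_len, stride) {
  budget <- max_len - n_query - 3L   # [CLS], 2 x [SEP]
  if (budget < 1L) abort("query alone exceeds the encoder maximum length")
  if (n_ctx <= budget) return(list(seq_len(n_ctx)))
  starts <- seq(1L, n_ctx, by = stride)
  wins <- lapply(starts, function(s) seq(s, min(s + budget - 1L, n_ctx)))
  keep <- c(TRUE, vapply(seq_along(wins)[-1], function(i) {
    utils::tail(wins[[i]], 1) > utils::tail(wins[[i - 1]], 1)
  }, logical(1)))
  wins[keep]
}
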