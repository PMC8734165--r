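#' Knowledge-selection attention over candidate relation vectors
#'
#' First step of the two-step knowledge fusion. In `"attention"` mode a
#' bilinear score between each token's hidden vector and each candidate
#' relation vector is softmax-normalized over relations,
#' `alpha[i, t] = softmax_t(h_i W1 r_t + b1)`, and each token receives the
#' weighted relation representation `k_i = sum_t alpha[i, t] r_t`. In
#' `"mean"` mode the relation vectors are averaged unweighted (identical for
#' every token), the simpler ablation of the selection step.
#'
#' @param hidden `k x d1` matrix of token hidden states.
#' @param relations `T x d2` matrix of candidate relation vectors (`T >= 1`).
#' @param W1 `d1 x d2` bilinear weight matrix.
#' @param b1 Scalar bias on the attention logits.
#' @param mode `"attention"` or `"mean"`.
#'
#' @return List with `k_mat` (`k x d2` per-token knowledge representation)
#'   and `alpha` (`k x T` attention weights).
#' @export
knowledge_select_attention <- function(hidden, relations, W1, b1 = 0,
                                       mode = c("attention", "mean")) {
  mode <- match.arg(mode)
  if (is.null(dim(relations))) relations <- matrix(relations, nrow = 1)
  if (!nrow(relations)) abort("at least one relation vector is required")
  k <- nrow(hidden)
  if (mode == "mean") {
    k_mat <- matrix(colMeans(relations), k, ncol(relations), byrow = TRUE)
    alpha <- matrix(1 / nrow(relations), k, nrow(relations))
    return(list(k_mat = k_mat, alpha = alpha))
  }
  logits <- hidden %*% W1 %*% t(relations) + b1
  alpha <- softmax_rows(logits)
  list(k_mat = alpha %*% relations, alpha = alpha)
}

#' Knowledge-context attention aligning tokens to the context
#'
#' Second fusion step: each token's knowledge representation attends over all
#' hidden states, `beta[i, j] = softmax_j(k_i W2 h_j + b2)`, and the
#' knowledge-enhanced representation is the convex combination
#' `h'_i = sum_j beta[i, j] h_j`.
#'
#' @param k_mat `k x d2` per-token knowledge representations.
#' @param hidden `k x d1` matrix of token hidden states.
#' @param W2 `d2 x d1` bilinear weight matrix.
#' @param b2 Scalar bias on the attention logits.
#'
#' @return List with `h_prime` (`k x d1`) and `beta` (`k x k`).
#' @export
knowledge_context_attention <- function(k_mat, hidden, W2, b2 = 0) {
  if (nrow(k_mat) != nrow(hidden)) abort("k_mat and hidden row counts differ")
  logits <- k_mat %*% W2 %*% t(hidden) + b2
  beta <- softmax_rows(logits)
  list(h_prime = beta %*% hidden, beta = beta)
}

#' Initialize the attention/fusion/span-head parameters
#'
#' @param d1 Encoder hidden size.
#' @param d2 Knowledge embedding dimension.
#' @param d_ff Feed-forward inner width of the span heads (defaults to `d1`).
#' @param seed RNG seed.
#' @return Named list of parameter matrices/vectors (class `krc_params`).
#' @export
init_head_params <- function(d1, d2, d_ff = d1, seed = 1L) {
  with_seed_(seed, {
    # Glorot-scaled normal init, the usual scheme for bilinear/linear layers
    # trained from scratch
    rm_ <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    p <- list(
      W1 = rm_(d1, d2), b1 = 0,
      W2 = rm_(d2, d1), b2 = 0,
      Wh = rm_(d1, d1), Whp = rm_(d1, d1), b = numeric(d1),
      W3s = rm_(2L * d1, d_ff), b3s = numeric(d_ff),
      W4s = rm_(d_ff, 1L), b4s = 0,
      W3e = rm_(2L * d1, d_ff), b3e = numeric(d_ff),
      W4e = rm_(d_ff, 1L), b4e = 0)
    structure(p, class = "krc_params", d1 = d1, d2 = d2, d_ff = d_ff)
  })
}

#' Fuse hidden and knowledge-enhanced states and predict span distributions
#'
#' With the knowledge path on, the fused representation is
#' `v_i = Wh h_i + Whp h'_i + b` and the span-head input is the concatenation
#' `u_i = [h'_i; v_i]`. With the knowledge path off (the plain
#' reading-comprehension ablation) the head consumes `u_i = [h_i; Wh h_i + b]`,
#' keeping the head shape and parameter count identical. Start and end
#' probability distributions over positions are softmaxes of a one-hidden-layer
#' feed-forward network with RELU, with separate parameters per head.
#'
#' @param hidden `k x d1` matrix of token hidden states.
#' @param h_prime `k x d1` knowledge-enhanced states (ignored when
#'   `use_kb = FALSE`).
#' @param params A `krc_params` list from [init_head_params()].
#' @param use_kb Logical; include the knowledge path.
#'
#' @return List with probability vectors `p_start`, `p_end` (each of length
#'   `k`, summing to one) and the intermediate `u`.
#' @export
fuse_and_predict <- function(hidden, h_prime, params, use_kb = TRUE) {
  fw <- fuse_predict_forward(hidden, h_prime, params, use_kb)
  if (!all(is.finite(fw$logit_s)) || !all(is.finite(fw$logit_e))) {
    abort("non-finite span logits")
  }
  list(p_start = fw$p_start, p_end = fw$p_end, u = fw$u)
}

fuse_predict_forward <- function(hidden, h_prime, params, use_kb = TRUE) {
  k <- nrow(hidden); d1 <- ncol(hidden)
  if (use_kb) {
    v <- hidden %*% params$Wh + h_prime %*% params$Whp +
      rep(params$b, each = k)
    u <- cbind(h_prime, v)
  } else {
    v <- hidden %*% params$Wh + rep(params$b, each = k)
    u <- cbind(hidden, v)
  }
  a_s <- u %*% params$W3s + rep(params$b3s, each = k)
  r_s <- pmax(a_s, 0)
  logit_s <- drop(r_s %*% params$W4s) + params$b4s
  a_e <- u %*% params$W3e + rep(params$b3e, each = k)
  r_e <- pmax(a_e, 0)
  logit_e <- drop(r_e %*% params$W4e) + params$b4e
  p_start <- drop(softmax_rows(matrix(logit_s, 1)))
  p_end <- drop(softmax_rows(matrix(logit_e, 1)))
  list(p_start = p_start, p_end = p_end, u = u, v = v,
       a_s = a_s, r_s = r_s, a_e = a_e, r_e = r_e,
       logit_s = logit_s, logit_e = logit_e)
}

#' Span cross-entropy loss
#'
#' The loss of one instance is the average negative log probability of the
#' gold start and end positions,
#' `-(log p_start[y_start] + log p_end[y_end]) / 2`; a batch loss is the mean
#' over instances. Null (unanswerable) instances use position 1, the `[CLS]`
#' sentinel, for both indices.
#'
#' @param p_start,p_end Probability vectors over the `k` packed positions.
#' @param y_start,y_end Gold 1-based positions (`1` = `[CLS]` = null).
#'
#' @return Non-negative scalar loss.
#' @export
span_loss <- function(p_start, p_end, y_start, y_end) {
  k <- length(p_start)
  if (y_start < 1 || y_start > k || y_end < 1 || y_end > k) {
    abort("gold index out of range")
  }
  -(log(p_start[y_start]) + log(p_end[y_end])) / 2
}

# full head forward with cache: selection attention, context attention,
# fusion, span distributions
head_forward <- function(hidden, relations, params, use_kb = TRUE,
                         kb_mode = c("attention", "mean")) {
  kb_mode <- match.arg(kb_mode)
  if (use_kb) {
    sel <- knowledge_select_attention(hidden, relations, params$W1, params$b1,
                                      mode = kb_mode)
    ctx <- knowledge_context_attention(sel$k_mat, hidden, params$W2, params$b2)
    h_prime <- ctx$h_prime
  } else {
    sel <- NULL; ctx <- NULL; h_prime <- NULL
  }
  fw <- fuse_predict_forward(hidden, h_prime, params, use_kb)
  c(fw, list(hidden = hidden, relations = relations, sel = sel, ctx = ctx,
             h_prime = h_prime, use_kb = use_kb, kb_mode = kb_mode))
}

# backward from gold indices through the head; returns parameter grads and
# the gradient on the encoder hidden states. Loss: span_loss at (ys, ye).
head_backward <- function(cache, params, y_start, y_end) {
  k <- nrow(cache$hidden); d1 <- ncol(cache$hidden)
  dlog_s <- cache$p_start / 2; dlog_s[y_start] <- dlog_s[y_start] - 0.5
  dlog_e <- cache$p_end / 2; dlog_e[y_end] <- dlog_e[y_end] - 0.5
  g <- list()
  du <- matrix(0, k, ncol(cache$u))
  # start head
  g$W4s <- t(cache$r_s) %*% dlog_s
  g$b4s <- sum(dlog_s)
  da <- outer(dlog_s, drop(params$W4s)) * (cache$a_s > 0)
  g$W3s <- t(cache$u) %*% da
  g$b3s <- colSums(da)
  du <- du + da %*% t(params$W3s)
  # end head
  g$W4e <- t(cache$r_e) %*% dlog_e
  g$b4e <- sum(dlog_e)
  da <- outer(dlog_e, drop(params$W4e)) * (cache$a_e > 0)
  g$W3e <- t(cache$u) %*% da
  g$b3e <- colSums(da)
  du <- du + da %*% t(params$W3e)
  du_left <- du[, seq_len(d1), drop = FALSE]
  du_v <- du[, d1 + seq_len(d1), drop = FALSE]
  hidden <- cache$hidden
  if (!cache$use_kb) {
    g$Wh <- t(hidden) %*% du_v
    g$b <- colSums(du_v)
    g$Whp <- matrix(0, d1, d1)
    g$W1 <- matrix(0, nrow(params$W1), ncol(params$W1)); g$b1 <- 0
    g$W2 <- matrix(0, nrow(params$W2), ncol(params$W2)); g$b2 <- 0
    dhidden <- du_left + du_v %*% t(params$Wh)
    return(list(grads = g, dhidden = dhidden))
  }
  h_prime <- cache$h_prime
  g$Wh <- t(hidden) %*% du_v
  g$Whp <- t(h_prime) %*% du_v
  g$b <- colSums(du_v)
  dhidden <- du_v %*% t(params$Wh)
  dh_prime <- du_left + du_v %*% t(params$Whp)
  # context attention: h' = beta %*% hidden, beta = softmax(k_mat W2 h^T + b2)
  beta <- cache$ctx$beta; k_mat <- cache$sel$k_mat
  dbeta <- dh_prime %*% t(hidden)
  dhidden <- dhidden + t(beta) %*% dh_prime
  dM <- softmax_rows_backward(beta, dbeta)
  g$W2 <- t(k_mat) %*% dM %*% hidden
  g$b2 <- sum(dM)
  dk_mat <- dM %*% hidden %*% t(params$W2)
  dhidden <- dhidden + t(dM) %*% k_mat %*% params$W2
  # selection attention
  R <- cache$relations
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  if (cache$kb_mode == "mean") {
    g$W1 <- matrix(0, nrow(params$W1), ncol(params$W1)); g$b1 <- 0
  } else {
    alpha <- cache$sel$alpha
    dalpha <- dk_mat %*% t(R)
    dN <- softmax_rows_backward(alpha, dalpha)
    g$W1 <- t(hidden) %*% dN %*% R
    g$b1 <- sum(dN)
    dhidden <- dhidden + dN %*% R %*% t(params$W1)
  }
  list(grads = g, dhidden = dhidden)
}

#' Assemble a knowledge-enhanced reading-comprehension model
#'
#' Couples a sequence encoder with the two-step knowledge attention and the
#' span-prediction head.
#'
#' @param encoder A `krc_encoder` from [init_encoder()] (or any object
#'   honoring the same contract).
#' @param d2 Knowledge embedding dimension (must match the TransE store).
#' @param use_kb Include the knowledge path; when `FALSE` the model is the
#'   plain reading-comprehension ablation and relation vectors are ignored.
#' @param kb_mode `"attention"` (bilinear selection over relation vectors) or
#'   `"mean"` (unweighted average).
#' @param d_ff Span-head feed-forward width.
#' @param seed RNG seed for head initialization.
#'
#' @return A `krc_model` object.
#' @export
krc_model <- function(encoder, d2 = 16L, use_kb = TRUE,
                      kb_mode = c("attention", "mean"), d_ff = NULL,
                      seed = 1L) {
  kb_mode <- match.arg(kb_mode)
  d1 <- encoder$spec$d1
  if (is.null(d_ff)) d_ff <- d1
  structure(list(encoder = encoder,
                 head = init_head_params(d1, d2, d_ff, seed = seed),
                 d2 = as.integer(d2), use_kb = use_kb, kb_mode = kb_mode),
            class = "krc_model")
}

#' @export
print.krc_model <- function(x, ...) {
  cat(sprintf("<krc_model> d1 = %d, d2 = %d, knowledge %s (%s)\n",
              x$encoder$spec$d1, x$d2, if (x$use_kb) "on" else "off",
              x$kb_mode))
  invisible(x)
}
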