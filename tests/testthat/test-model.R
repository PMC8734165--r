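test_that("selection attention matches its per-token loop oracle", {
  set.seed(101)
  for (trial in 1:20) {
    k <- sample(2:8, 1); d1 <- sample(2:16, 1); d2 <- sample(2:8, 1)
    Tn <- sample(1:3, 1)
    cs <- rand_case(k, d1, d2, Tn)
    got <- knowledge_select_attention(cs$hidden, cs$relations, cs$W1, 0.3)
    want <- oracle_select_attention(cs$hidden, cs$relations, cs$W1, 0.3)
    expect_lt(max(abs(got$k_mat - want$k_mat)), 1e-5)
    expect_lt(max(abs(got$alpha - want$alpha)), 1e-5)
  }
})

test_that("context attention matches its double-loop oracle", {
  set.seed(102)
  for (trial in 1:20) {
    k <- sample(2:8, 1); d1 <- sample(2:16, 1); d2 <- sample(2:8, 1)
    cs <- rand_case(k, d1, d2, 2)
    km <- matrix(rnorm(k * d2), k, d2)
    got <- knowledge_context_attention(km, cs$hidden, cs$W2, -0.2)
    want <- oracle_context_attention(km, cs$hidden, cs$W2, -0.2)
    expect_lt(max(abs(got$h_prime - want$h_prime)), 1e-5)
    expect_lt(max(abs(got$beta - want$beta)), 1e-5)
  }
})

test_that("a single relation vector passes through both modes exactly", {
  set.seed(103)
  h <- matrix(rnorm(5 * 8), 5, 8)
  r <- matrix(rnorm(1 * 4), 1, 4)
  W1 <- matrix(rnorm(8 * 4), 8, 4)
  for (mode in c("attention", "mean")) {
    out <- knowledge_select_attention(h, r, W1, mode = mode)
    expect_equal(out$alpha, matrix(1, 5, 1))
    for (i in 1:5) expect_equal(out$k_mat[i, ], drop(r))
  }
})

test_that("identical relation vectors give uniform attention weights", {
  set.seed(104)
  h <- matrix(rnorm(4 * 6), 4, 6)
  r1 <- rnorm(5)
  r <- rbind(r1, r1, r1)
  rownames(r) <- NULL
  W1 <- matrix(rnorm(6 * 5), 6, 5)
  out <- knowledge_select_attention(h, r, W1)
  expect_equal(out$alpha, matrix(1 / 3, 4, 3))
  for (i in 1:4) expect_equal(out$k_mat[i, ], r1)
})

test_that("mean mode averages relations identically for every token", {
  set.seed(105)
  h <- matrix(rnorm(3 * 4), 3, 4)
  r <- matrix(rnorm(3 * 5), 3, 5)
  out <- knowledge_select_attention(h, r, NULL, mode = "mean")
  for (i in 1:3) expect_equal(out$k_mat[i, ], colMeans(r))
})

test_that("context attention degenerates correctly", {
  # sequence of length one: beta = 1, h' = h
  h1 <- matrix(rnorm(1 * 4), 1, 4)
  k1 <- matrix(rnorm(1 * 3), 1, 3)
  W2 <- matrix(rnorm(3 * 4), 3, 4)
  out <- knowledge_context_attention(k1, h1, W2)
  expect_equal(out$beta, matrix(1, 1, 1))
  expect_equal(out$h_prime, h1)
  # identical hidden rows: h'_i equals that row whatever beta is
  h <- matrix(rep(rnorm(4), each = 5), 5, 4)
  km <- matrix(rnorm(5 * 3), 5, 3)
  out2 <- knowledge_context_attention(km, h, W2)
  for (i in 1:5) expect_equal(out2$h_prime[i, ], h[1, ])
  expect_error(knowledge_context_attention(km[1:2, ], h, W2), "row counts")
})

test_that("span head matches the per-position oracle, with and without kb", {
  set.seed(106)
  for (trial in 1:20) {
    k <- sample(2:8, 1); d1 <- sample(2:12, 1); d2 <- sample(2:6, 1)
    params <- init_head_params(d1, d2, seed = trial)
    h <- matrix(rnorm(k * d1), k, d1)
    hp <- matrix(rnorm(k * d1), k, d1)
    for (use_kb in c(TRUE, FALSE)) {
      got <- fuse_and_predict(h, hp, params, use_kb = use_kb)
      want <- oracle_fuse_predict(h, hp, params, use_kb = use_kb)
      expect_lt(max(abs(got$p_start - want$p_start)), 1e-5)
      expect_lt(max(abs(got$p_end - want$p_end)), 1e-5)
      expect_equal(sum(got$p_start), 1, tolerance = 1e-6)
      expect_equal(sum(got$p_end), 1, tolerance = 1e-6)
    }
  }
})

test_that("constant inputs yield uniform span distributions", {
  d1 <- 6
  params <- init_head_params(d1, 3, seed = 9)
  h <- matrix(rep(rnorm(d1), each = 4), 4, d1)
  hp <- matrix(rep(rnorm(d1), each = 4), 4, d1)
  out <- fuse_and_predict(h, hp, params)
  expect_equal(out$p_start, rep(1 / 4, 4))
  expect_equal(out$p_end, rep(1 / 4, 4))
})

test_that("span loss closed forms hold", {
  onehot <- function(k, i) { p <- rep(0, k); p[i] <- 1; p }
  expect_equal(span_loss(onehot(6, 3), onehot(6, 4), 3, 4), 0)
  expect_equal(span_loss(rep(0.1, 10), rep(0.1, 10), 2, 5), log(10),
               tolerance = 1e-9)
  expect_equal(log(10), 2.302585, tolerance = 1e-6)
  # batch loss is the mean of per-instance losses
  a <- span_loss(rep(0.25, 4), rep(0.25, 4), 1, 1)
  b <- span_loss(onehot(4, 2), onehot(4, 3), 2, 3)
  expect_equal(mean(c(a, b)), (a + b) / 2)
  expect_error(span_loss(rep(0.25, 4), rep(0.25, 4), 0, 2), "out of range")
  expect_error(span_loss(rep(0.25, 4), rep(0.25, 4), 1, 5), "out of range")
})

test_that("with the knowledge path off, relation vectors cannot matter", {
  v <- build_vocab(c("q", "x", "y"))
  enc <- init_encoder(tiny_encoder_spec(d1 = 16L, d_ff = 16L), v, seed = 3)
  model <- krc_model(enc, d2 = 4, use_kb = FALSE, seed = 4)
  ids <- c(2L, 5L, 3L, 6L, 7L, 3L)
  seg <- c(0L, 0L, 0L, 1L, 1L, 1L)
  fwd <- krc:::encoder_forward(enc, ids, seg)
  set.seed(5)
  o1 <- krc:::head_forward(fwd$hidden, matrix(rnorm(4), 1, 4), model$head,
                           use_kb = FALSE)
  o2 <- krc:::head_forward(fwd$hidden, matrix(rnorm(12), 3, 4), model$head,
                           use_kb = FALSE)
  expect_identical(o1$p_start, o2$p_start)
  expect_identical(o1$p_end, o2$p_end)
})

test_that("head and encoder gradients agree with finite differences end to end", {
  v <- build_vocab(c("q", "x", "y", "z"))
  enc <- init_encoder(tiny_encoder_spec(d1 = 8L, n_heads = 2L, d_ff = 12L),
                      v, seed = 5)
  model <- krc_model(enc, d2 = 4, use_kb = TRUE, seed = 6)
  ids <- c(2L, 5L, 6L, 3L, 7L, 8L, 3L)
  seg <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L)
  set.seed(31)
  R <- matrix(rnorm(3 * 4), 3, 4)
  ys <- 5L; ye <- 6L
  loss_fn <- function(enc_p, head_p) {
    e2 <- enc; e2$params <- enc_p
    fwd <- krc:::encoder_forward(e2, ids, seg)
    hc <- krc:::head_forward(fwd$hidden, R, head_p, use_kb = TRUE)
    span_loss(hc$p_start, hc$p_end, ys, ye)
  }
  fwd <- krc:::encoder_forward(enc, ids, seg)
  hc <- krc:::head_forward(fwd$hidden, R, model$head, use_kb = TRUE)
  hb <- krc:::head_backward(hc, model$head, ys, ye)
  genc <- krc:::encoder_backward(enc, fwd$cache, hb$dhidden)
  eps <- 1e-6
  for (nm in c("W1", "W2", "Wh", "Whp", "W3s", "W4e", "b", "b3s")) {
    i <- sample(length(model$head[[nm]]), 1)
    hp_up <- model$head; hp_up[[nm]][i] <- hp_up[[nm]][i] + eps
    hp_dn <- model$head; hp_dn[[nm]][i] <- hp_dn[[nm]][i] - eps
    num <- (loss_fn(enc$params, hp_up) - loss_fn(enc$params, hp_dn)) / (2 * eps)
    expect_equal(as.numeric(hb$grads[[nm]])[i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
  for (nm in c("tok_emb", "L1.Wv", "L2.ln2_g")) {
    i <- sample(length(enc$params[[nm]]), 1)
    ep_up <- enc$params; ep_up[[nm]][i] <- ep_up[[nm]][i] + eps
    ep_dn <- enc$params; ep_dn[[nm]][i] <- ep_dn[[nm]][i] - eps
    num <- (loss_fn(ep_up, model$head) - loss_fn(ep_dn, model$head)) / (2 * eps)
    expect_equal(as.numeric(genc[[nm]])[i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("one small gradient step on an instance lowers its span loss", {
  v <- build_vocab(c("q", "x", "y", "z"))
  enc <- init_encoder(tiny_encoder_spec(d1 = 8L, d_ff = 8L), v, seed = 11)
  model <- krc_model(enc, d2 = 4, use_kb = TRUE, seed = 12)
  ids <- c(2L, 5L, 3L, 6L, 7L, 6L, 3L)
  seg <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L)
  set.seed(13)
  R <- matrix(rnorm(2 * 4), 2, 4)
  ys <- 4L; ye <- 5L
  fwd <- krc:::encoder_forward(enc, ids, seg)
  hc <- krc:::head_forward(fwd$hidden, R, model$head, use_kb = TRUE)
  l0 <- span_loss(hc$p_start, hc$p_end, ys, ye)
  hb <- krc:::head_backward(hc, model$head, ys, ye)
  genc <- krc:::encoder_backward(enc, fwd$cache, hb$dhidden)
  lr <- 1e-4
  enc2 <- enc
  for (nm in names(enc2$params)) {
    enc2$params[[nm]] <- enc2$params[[nm]] - lr * genc[[nm]]
  }
  head2 <- model$head
  for (nm in names(head2)) head2[[nm]] <- head2[[nm]] - lr * hb$grads[[nm]]
  fwd2 <- krc:::encoder_forward(enc2, ids, seg)
  hc2 <- krc:::head_forward(fwd2$hidden, R, head2, use_kb = TRUE)
  expect_lt(span_loss(hc2$p_start, hc2$p_end, ys, ye), l0)
})
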