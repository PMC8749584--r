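# Structural, masking and gradient correctness of the recurrent branch.

test_that("biGRU output concatenates both directions: width 2H", {
  set.seed(11)
  cfg <- triage_config("fast", emb_dim = 8L, hidden = 128L)
  p <- init_rnn_params(20L, cfg, seed = 1L)
  x <- matrix(rnorm(6 * 8, sd = 0.3), 6, 8)
  H <- bigru_encode(x, p)
  expect_equal(dim(H), c(6L, 256L))
  expect_true(all(is.finite(H)))
  expect_error(bigru_encode(x, p, mask = rep(FALSE, 6)), "entirely padding")
})

test_that("the compiled GRU matches a plain-R reference recurrence", {
  set.seed(12)
  cfg <- tiny_config()
  H <- cfg$hidden
  for (trial in 1:5) {
    p <- init_rnn_params(15L, cfg, seed = trial)
    Tn <- sample(1:7, 1)
    x <- matrix(rnorm(Tn * cfg$emb_dim, sd = 0.5), Tn, cfg$emb_dim)
    got <- bigru_encode(x, p)
    fwd <- ref_gru(x, p$gru_Wf, p$gru_bf, p$gru_Uf, H)
    bwd <- ref_gru(x[Tn:1, , drop = FALSE], p$gru_Wb, p$gru_bb, p$gru_Ub, H)
    expect_equal(got[, 1:H], fwd, tolerance = 1e-12)
    expect_equal(got[, (H + 1):(2 * H)], bwd[Tn:1, , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("single-token sequences condition both directions on that token", {
  cfg <- tiny_config()
  p <- init_rnn_params(15L, cfg, seed = 3L)
  x <- matrix(rnorm(cfg$emb_dim), 1, cfg$emb_dim)
  H1 <- bigru_encode(x, p)
  # forward and backward passes over one token are one GRU step each
  expect_equal(H1[, 1:cfg$hidden, drop = FALSE],
               ref_gru(x, p$gru_Wf, p$gru_bf, p$gru_Uf, cfg$hidden),
               tolerance = 1e-12)
  expect_equal(H1[, cfg$hidden + 1:cfg$hidden, drop = FALSE],
               ref_gru(x, p$gru_Wb, p$gru_bb, p$gru_Ub, cfg$hidden),
               tolerance = 1e-12)
})

test_that("trailing padding influences nothing", {
  cfg <- tiny_config()
  p <- init_rnn_params(15L, cfg, seed = 4L)
  b <- random_batch(B = 5L, Tn = 8L, V = 15L, seed = 5L)
  fw1 <- rnn_forward_batch(p, cfg, b$ids, b$lengths)
  wide <- cbind(b$ids, matrix(0L, 5L, 4L))     # more PAD columns
  fw2 <- rnn_forward_batch(p, cfg, wide, b$lengths)
  expect_equal(fw1$probs, fw2$probs, tolerance = 1e-12)
  expect_equal(fw1$penultimate, fw2$penultimate, tolerance = 1e-12)
  # perturbing the PAD embedding row changes nothing either
  p2 <- p
  p2$emb[1, ] <- rnorm(cfg$emb_dim)
  fw3 <- rnn_forward_batch(p2, cfg, b$ids, b$lengths)
  expect_equal(fw1$probs, fw3$probs, tolerance = 1e-12)
})

test_that("attention weights are a probability distribution per layer", {
  cfg <- tiny_config()
  p <- init_rnn_params(25L, cfg, seed = 6L)
  b <- random_batch(B = 7L, Tn = 9L, V = 25L, seed = 7L)
  fw <- rnn_forward_batch(p, cfg, b$ids, b$lengths)
  mask <- outer(b$lengths, seq_len(max(b$lengths)), ">=")
  for (al in fw$attention) {
    expect_true(all(al >= 0))
    expect_equal(rowSums(al), rep(1, 7), tolerance = 1e-6)
    expect_true(all(al[!mask] == 0))
  }
})

test_that("uniform scorers give uniform weights; T = 1 gives weight one", {
  cfg <- tiny_config(att_layers = 2L)
  p <- init_rnn_params(15L, cfg, seed = 8L)
  att <- p[grep("^att", names(p))]
  for (nm in names(att)) att[[nm]] <- att[[nm]] * 0   # constant logits
  hs <- matrix(rnorm(4 * (2 * cfg$hidden)), 4, 2 * cfg$hidden)
  pooled <- attention_pool(hs, att, n_layers = 2L)
  expect_equal(pooled$weights[[1]], rep(0.25, 4))
  expect_equal(pooled$weights[[2]], rep(0.25, 4))
  # uniform re-weighting is the identity, so the context is the plain mean
  expect_equal(pooled$context, colMeans(hs), tolerance = 1e-12)

  one <- attention_pool(hs[1, , drop = FALSE],
                        p[grep("^att", names(p))], n_layers = 2L)
  expect_equal(one$weights[[1]], 1)
  expect_equal(one$weights[[2]], 1)
  expect_equal(one$context, hs[1, ], tolerance = 1e-12)
})

test_that("pooled context equals the direct weighted summation", {
  cfg <- tiny_config(att_layers = 2L)
  for (trial in 1:5) {
    p <- init_rnn_params(15L, cfg, seed = 20L + trial)
    att <- p[grep("^att", names(p))]
    Tn <- sample(2:6, 1)
    D <- 2L * cfg$hidden
    hs <- matrix(rnorm(Tn * D), Tn, D)
    pooled <- attention_pool(hs, att, n_layers = 2L)
    a1 <- pooled$weights[[1]]; a2 <- pooled$weights[[2]]
    reweighted <- hs * (Tn * a1)          # layer 1 re-scales each position
    ctx <- colSums(reweighted * a2)       # layer 2 pools
    expect_equal(pooled$context, ctx, tolerance = 1e-10)
  }
})

test_that("branch outputs live on the simplex with a 64-unit penultimate", {
  cfg <- triage_config("fast", emb_dim = 8L, hidden = 6L)
  p <- init_rnn_params(30L, cfg, seed = 9L)
  model <- structure(list(params = p, config = cfg, branch_kind = "rnn"),
                     class = "triage_branch")
  v <- build_vocab(paste(letters, collapse = " "))
  for (i in 1:5) {
    enc <- encode(sample(letters, sample(2:9, 1)), v, max_len = 12L)
    out <- rnn_forward(enc, model)
    expect_length(out$penultimate, 64L)
    expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
    expect_true(all(out$probabilities >= 0))
  }
})

test_that("analytic gradients match finite differences (rnn)", {
  cfg <- tiny_config()
  p <- init_rnn_params(12L, cfg, seed = 31L)
  b <- random_batch(B = 3L, Tn = 7L, V = 12L, seed = 32L)
  y <- c(1L, 0L, 1L)
  fw <- rnn_forward_batch(p, cfg, b$ids, b$lengths, want_grad = TRUE)
  ga <- rnn_backward_batch(p, cfg, fw,
                           dlogits = softmax_ce_dlogits(fw$probs, y))
  gn <- num_grad(p, function(pp) {
    cross_entropy(rnn_forward_batch(pp, cfg, b$ids, b$lengths)$probs, y)
  })
  expect_lt(max_rel_err(ga, gn), 1e-4)
})
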