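# Embedding, hierarchical attention, BiLSTM and Transformer: closed-form
# cases and masking/symmetry oracles.

make_seq_params <- function(H, A = 3L, layers = 1L, seed = 1, dict_size = 6L) {
  set.seed(seed)
  rnd <- function(a, b, sd = 0.4) matrix(rnorm(a * b, sd = sd), a, b)
  W <- 2L * H
  p <- list("seq.emb" = rnd(dict_size, H), "seq.level_emb" = rnd(3, H),
            "ha.W1" = rnd(H, A), "ha.b" = matrix(0, 1, A), "ha.W2" = rnd(A, 1))
  for (l in seq_len(layers)) {
    nin <- if (l == 1L) H else W
    for (dir in c("f", "b")) {
      p[[sprintf("lstm%d.%s.Wx", l, dir)]] <- rnd(nin, 4 * H)
      p[[sprintf("lstm%d.%s.Wh", l, dir)]] <- rnd(H, 4 * H)
      p[[sprintf("lstm%d.%s.b", l, dir)]] <- matrix(0, 1, 4 * H)
    }
  }
  p[["trans.Wq"]] <- rnd(W, W); p[["trans.Wk"]] <- rnd(W, W)
  p[["trans.Wv"]] <- rnd(W, W); p[["trans.Wo"]] <- rnd(W, W)
  p[["trans.ln1.g"]] <- matrix(1, 1, W); p[["trans.ln1.b"]] <- matrix(0, 1, W)
  p[["trans.ffn.W1"]] <- rnd(W, 2 * W); p[["trans.ffn.b1"]] <- matrix(0, 1, 2 * W)
  p[["trans.ffn.W2"]] <- rnd(2 * W, W); p[["trans.ffn.b2"]] <- matrix(0, 1, W)
  p[["trans.ln2.g"]] <- matrix(1, 1, W); p[["trans.ln2.b"]] <- matrix(0, 1, W)
  p
}

test_that("token embedding is a deterministic lookup equal to one-hot times the weight matrix", {
  p <- make_seq_params(4)
  X <- embed_tokens(c(2L, 3L, 2L), mask = c(1, 1, 1), levels = c(3L, 3L, 3L), p)
  expect_equal(X[1, ], X[3, ])   # same token, same level -> same row
  # algebraic identity: one-hot e_i x emb == emb row i (plus level embedding)
  oh <- matrix(0, 1, 6); oh[1, 3] <- 1
  expect_equal(X[1, ], as.numeric(oh %*% p[["seq.emb"]] + p[["seq.level_emb"]][3, ]),
               tolerance = 1e-12)
  # pad position is a zero vector
  Xp <- embed_tokens(c(2L, 0L), mask = c(1, 0), levels = c(3L, 0L), p)
  expect_true(all(Xp[2, ] == 0))
  expect_error(embed_tokens(c(99L), mask = 1, levels = 3L, p), "range")
})

test_that("hierarchical attention normalizes over real positions and reduces to closed forms", {
  p <- make_seq_params(4)
  set.seed(2); X <- matrix(rnorm(20), 5, 4)
  ha <- hierarchical_attention(X, mask = rep(1, 5), p)
  expect_equal(sum(ha$weights), 1, tolerance = 1e-9)
  expect_equal(ha$X_atten, X * as.numeric(ha$weights))
  expect_equal(ha$h_atten, matrix(colSums(ha$X_atten), 1), tolerance = 1e-12)
  expect_equal(ha$expanded, matrix(rep(ha$h_atten, each = 5), 5), tolerance = 1e-12)
  # T = 1: the single weight is 1 and the pooled vector is the input
  ha1 <- hierarchical_attention(X[1, , drop = FALSE], mask = 1, p)
  expect_equal(as.numeric(ha1$weights), 1)
  expect_equal(ha1$expanded, X[1, , drop = FALSE])
  # zero scoring vector gives uniform attention (mean pooling)
  p0 <- p; p0[["ha.W2"]][] <- 0
  ha0 <- hierarchical_attention(X, rep(1, 5), p0)
  expect_equal(as.numeric(ha0$weights), rep(0.2, 5))
  expect_equal(ha0$h_atten, matrix(colSums(X) / 5, 1), tolerance = 1e-12)
  # pad extension leaves weights on real tokens unchanged
  Xext <- rbind(X, matrix(0, 2, 4))
  hae <- hierarchical_attention(Xext, mask = c(rep(1, 5), 0, 0), p)
  expect_equal(hae$weights[1:5, ], ha$weights[1:5, ], tolerance = 1e-12)
  expect_true(all(hae$weights[6:7, ] == 0))
  expect_error(hierarchical_attention(X, mask = rep(0, 5), p), "masked")
})

test_that("BiLSTM output concatenates both directions and respects reversal symmetry", {
  H <- 4L
  p <- make_seq_params(H, layers = 1L, seed = 5)
  cfg <- gsfl_config(seq_layers = 1L, seq_hidden = H, n_heads = 2L,
                     gnn_hidden = 8L, reduction_ratio = 4L)
  set.seed(6); X <- matrix(rnorm(3 * H), 3, H)
  out <- bilstm_encode(X, mask = rep(1, 3), p, cfg)
  expect_identical(dim(out), c(3L, 2L * H))
  # tie the two directions' weights: reversing the input swaps the halves
  p_tied <- p
  for (nm in c("Wx", "Wh", "b"))
    p_tied[[sprintf("lstm1.b.%s", nm)]] <- p_tied[[sprintf("lstm1.f.%s", nm)]]
  o1 <- bilstm_encode(X, rep(1, 3), p_tied, cfg)
  o2 <- bilstm_encode(X[3:1, , drop = FALSE], rep(1, 3), p_tied, cfg)
  expect_equal(o2[3:1, c(H + 1:H, 1:H)], o1, tolerance = 1e-10,
               ignore_attr = TRUE)
  # T = 1 still yields the concatenated width
  o3 <- bilstm_encode(X[1, , drop = FALSE], 1, p, cfg)
  expect_identical(dim(o3), c(1L, 2L * H))
  expect_error(bilstm_encode(X[0, , drop = FALSE], numeric(0), p, cfg),
               "zero-length")
})

test_that("the default sequence-branch width is twice the 128-unit hidden size", {
  cfg <- gsfl_config()
  expect_identical(2L * cfg$seq_hidden, 256L)
  p <- make_seq_params(8L, layers = 3L, seed = 11)
  cfg2 <- gsfl_config(seq_layers = 3L, seq_hidden = 8L, n_heads = 2L)
  set.seed(12); X <- matrix(rnorm(4 * 8), 4, 8)
  out <- bilstm_encode(X, rep(1, 4), p, cfg2)
  expect_identical(ncol(out), 2L * cfg2$seq_hidden)
})

test_that("the Transformer block preserves shape, masks pads, and is deterministic at evaluation", {
  H <- 4L; W <- 2L * H
  p <- make_seq_params(H, seed = 13)
  cfg <- gsfl_config(seq_layers = 1L, seq_hidden = H, n_heads = 2L)
  set.seed(14); S <- matrix(rnorm(5 * W), 5, W)
  msk <- c(1, 1, 1, 1, 0)
  S[5, ] <- 0
  out <- transformer_encode(S, msk, p, cfg)
  expect_identical(dim(out), dim(S))
  expect_identical(out, transformer_encode(S, msk, p, cfg))
  # perturbing a padded position leaves unmasked outputs unchanged
  S2 <- S; S2[5, ] <- rnorm(W)
  out2 <- transformer_encode(S2, msk, p, cfg)
  expect_equal(out2[1:4, ], out[1:4, ], tolerance = 1e-10)
  expect_true(all(out[5, ] == 0))
})

test_that("the sequence branch runs end to end, also with hierarchical attention ablated", {
  d <- generate_toy_dataset(8, seed = 31)
  for (use_ha in c(TRUE, FALSE)) {
    cfg <- gsfl_config(seq_layers = 2L, seq_hidden = 8L, n_heads = 2L,
                       gnn_hidden = 8L, attn_width = 4L, use_ha = use_ha)
    vocab <- default_fg_vocab()
    dict <- build_token_dictionary(lapply(d$smiles, tokenize_smiles, fg_vocab = vocab))
    enc <- lapply(d$smiles, function(s)
      encode_sequence(tokenize_smiles(s, vocab), dict, max_len = 40))
    sb <- gsfl:::batch_sequences(enc)
    P <- gsfl_init(cfg, dict$size)
    out <- gsfl:::.seq_branch(sb, P, cfg)
    expect_identical(dim(out), c(sb$B * sb$Tlen, 2L * cfg$seq_hidden))
    expect_true(all(is.finite(out)))
  }
})
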