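# Message passing and feature attention: closed-form cases, a brute-force
# loop oracle, and structural invariants.

make_graph_params <- function(d, seed = 1) {
  set.seed(seed)
  rnd <- function(a, b) matrix(rnorm(a * b, sd = 0.3), a, b)
  list("graph.W_iv" = rnd(133, d), "graph.W_ie" = rnd(14, d),
       "graph.W_edge" = rnd(d, d),
       "graph.comm1.W1" = rnd(2 * d, d), "graph.comm1.b1" = matrix(0, 1, d),
       "graph.comm1.W2" = rnd(d, d), "graph.comm1.b2" = matrix(0, 1, d),
       "graph.readout.W1" = rnd(2 * d + 133, d),
       "graph.readout.b1" = matrix(0, 1, d),
       "graph.readout.W2" = rnd(d, d), "graph.readout.b2" = matrix(0, 1, d),
       "fa.W2" = rnd(d, d %/% 2), "fa.W1" = rnd(d %/% 2, d))
}

test_that("hidden-state initialization applies the projections with ReLU and the documented shapes", {
  fx <- worked_example_fixtures()$tacrine_like
  g <- build_mol_graph(fx$smiles)
  p <- make_graph_params(64)
  st <- graph_init_hidden(g, p)
  expect_identical(dim(st$h_v), c(16L, 64L))
  expect_identical(dim(st$h_e), c(36L, 64L))   # 2 x 18 directed edges
  expect_true(all(st$h_v >= 0) && all(st$h_e >= 0))
  # zero features propagate to zero hidden states
  gz <- g; gz$atom_features[] <- 0; gz$bond_features[] <- 0
  stz <- graph_init_hidden(gz, p)
  expect_true(all(stz$h_v == 0) && all(stz$h_e == 0))
  # with non-negative identity-like weights ReLU is inactive
  p2 <- p
  p2[["graph.W_iv"]] <- diag(1, 133, 64)
  st2 <- graph_init_hidden(g, p2)
  expect_equal(st2$h_v, g$atom_features %*% p2[["graph.W_iv"]])
})

test_that("one message-passing step matches an explicit loop oracle on a 3-atom path", {
  g <- build_mol_graph("CCO")
  d <- 4L
  p <- make_graph_params(d, seed = 7)
  st <- graph_init_hidden(g, p)
  out <- message_pass_step(st, g, p, k = 1L)

  # oracle: explicit loops over atoms and directed edges
  h_v <- st$h_v; h_e <- st$h_e
  m <- matrix(0, g$n_atoms, d)
  for (a in seq_len(g$n_atoms)) {
    incoming <- which(g$edges[, 2] == a)
    if (length(incoming)) {
      hs <- h_e[incoming, , drop = FALSE]
      m[a, ] <- colSums(hs) * apply(hs, 2, max)
    }
  }
  z <- cbind(m, h_v)
  h1 <- pmax(z %*% p[["graph.comm1.W1"]], 0)
  h_v_new <- h1 %*% p[["graph.comm1.W2"]]
  h_e_new <- matrix(0, nrow(h_e), d)
  for (e in seq_len(nrow(g$edges)))
    h_e_new[e, ] <- pmax(h_e[e, ] + (h_v_new[g$edges[e, 1], ] - h_e[e, ]) %*%
                           p[["graph.W_edge"]], 0)
  expect_equal(out$m_v, m, tolerance = 1e-6)
  expect_equal(out$h_v, h_v_new, tolerance = 1e-6)
  expect_equal(out$h_e, h_e_new, tolerance = 1e-6)
})

test_that("message passing degenerate cases: isolated atoms, zero edge weights, singleton aggregation", {
  d <- 4L
  p <- make_graph_params(d, seed = 3)
  # single atom: zero message at every step
  g1 <- build_mol_graph("C")
  st <- graph_init_hidden(g1, p)
  out <- message_pass_step(st, g1, p)
  expect_true(all(out$m_v == 0))
  # W_edge = 0 freezes edge states at h_e0 (ReLU of non-negatives)
  g2 <- build_mol_graph("CCO")
  p0 <- p; p0[["graph.W_edge"]][] <- 0
  st2 <- graph_init_hidden(g2, p0)
  out2 <- message_pass_step(st2, g2, p0)
  expect_equal(out2$h_e, st2$h_e)
  # two-atom graph: sum and max over a singleton edge set coincide
  g3 <- build_mol_graph("CO")
  st3 <- graph_init_hidden(g3, p)
  out3 <- message_pass_step(st3, g3, p)
  for (a in 1:2) {
    e_in <- which(g3$edges[, 2] == a)
    expect_equal(out3$m_v[a, ], st3$h_e[e_in, ] * st3$h_e[e_in, ], tolerance = 1e-12)
  }
})

test_that("readout produces per-atom vectors, composes with message passing, and is deterministic", {
  g <- build_mol_graph("CCO")
  d <- 4L
  p <- make_graph_params(d, seed = 5)
  st <- graph_init_hidden(g, p)
  st1 <- message_pass_step(st, g, p, 1L)
  h_final <- readout_nodes(st1, g, p)
  expect_identical(dim(h_final), c(3L, d))
  expect_identical(h_final, readout_nodes(st1, g, p))
  # matches the internal single-batch branch with L = 1, no feature attention
  cfg <- gsfl_config(gnn_layers = 1L, gnn_hidden = d, use_fa = FALSE,
                     reduction_ratio = 2L)
  batch <- gsfl:::batch_graphs(list(g))
  expect_equal(gsfl:::.graph_branch(batch, p, cfg), h_final, tolerance = 1e-12)
})

test_that("feature attention reduces to closed forms and keeps weights strictly inside (0,1)", {
  d <- 4L
  p <- make_graph_params(d, seed = 9)
  h <- matrix(rnorm(12), 3, d)
  # zero input stays zero
  expect_true(all(feature_attention(h * 0, p) == 0))
  # zero excitation weights give c = 0.5 exactly
  p0 <- p; p0[["fa.W1"]][] <- 0; p0[["fa.W2"]][] <- 0
  expect_equal(feature_attention(h, p0), 0.5 * h, tolerance = 1e-12)
  # closed-form oracle for the excitation operator
  g_sum <- matrix(colSums(h), 1); g_max <- matrix(apply(h, 2, max), 1)
  cw <- 1 / (1 + exp(-((pmax(g_sum %*% p[["fa.W2"]], 0) +
                        pmax(g_max %*% p[["fa.W2"]], 0)) %*% p[["fa.W1"]])))
  expect_equal(feature_attention(h, p), sweep(h, 2, as.numeric(cw), "*"),
               tolerance = 1e-10)
  expect_true(all(cw > 0 & cw < 1))
  # magnitude never grows
  expect_true(all(abs(feature_attention(h, p)) <= abs(h) + 1e-12))
  # singleton: both pooled descriptors equal the single atom vector
  h1 <- h[1, , drop = FALSE]
  cw1 <- 1 / (1 + exp(-((pmax(h1 %*% p[["fa.W2"]], 0) * 2) %*% p[["fa.W1"]])))
  expect_equal(feature_attention(h1, p), h1 * as.numeric(cw1), tolerance = 1e-10)
  expect_error(feature_attention(h[0, , drop = FALSE], p), "at least one atom")
})

test_that("the full graph branch is permutation-equivariant and finite on random molecules", {
  cfg <- gsfl_config(gnn_layers = 3L, gnn_hidden = 16L, reduction_ratio = 4L)
  P <- gsfl_init(cfg, dict_size = 8L)
  d <- generate_toy_dataset(30, seed = 21)
  for (s in d$smiles[1:6]) {
    g <- build_mol_graph(s)
    out <- gsfl:::.graph_branch(gsfl:::batch_graphs(list(g)), P, cfg)
    expect_true(all(is.finite(out)))
    # permute atoms, remap edges: output rows permute identically
    perm <- sample(g$n_atoms)
    gp <- g
    gp$atom_features <- g$atom_features[perm, , drop = FALSE]
    inv <- integer(g$n_atoms); inv[perm] <- seq_len(g$n_atoms)
    gp$edges <- matrix(inv[g$edges], ncol = 2,
                       dimnames = dimnames(g$edges))
    outp <- gsfl:::.graph_branch(gsfl:::batch_graphs(list(gp)), P, cfg)
    expect_equal(outp, out[perm, , drop = FALSE], tolerance = 1e-8)
  }
  # batched outputs are finite over many molecules at once
  gb <- gsfl:::batch_graphs(build_mol_graphs(d$smiles))
  expect_true(all(is.finite(gsfl:::.graph_branch(gb, P, cfg))))
})
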