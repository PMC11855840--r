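# Pooling, fusion, prediction head and the two loss terms.

test_that("global attention pooling is convex and reduces to identities", {
  set.seed(1)
  w <- matrix(rnorm(4), 4, 1)
  x <- matrix(rnorm(4), 1, 4)
  expect_equal(global_attention_pool(x, gate_w = w), x, tolerance = 1e-12)
  # identical items pool to the common vector
  xx <- x[rep(1, 5), , drop = FALSE]
  expect_equal(global_attention_pool(xx, gate_w = w), x, tolerance = 1e-12)
  # convexity: pooled vector lies within the coordinate-wise range
  set.seed(2); y <- matrix(rnorm(20), 5, 4)
  pooled <- global_attention_pool(y, gate_w = w)
  expect_true(all(pooled >= apply(y, 2, min) - 1e-12 &
                  pooled <= apply(y, 2, max) + 1e-12))
  expect_error(global_attention_pool(y[0, , drop = FALSE], gate_w = w), "empty")
})

test_that("weighted fusion is the documented affine map and linear in each branch", {
  d <- 4L
  set.seed(3)
  p <- list("fusion.W_s" = matrix(rnorm(d * d), d, d),
            "fusion.W_g" = matrix(rnorm(d * d), d, d),
            "fusion.b" = matrix(rnorm(d), 1, d))
  Hs <- matrix(rnorm(2 * d), 2, d); Hg <- matrix(rnorm(2 * d), 2, d)
  H <- weighted_fusion(Hs, Hg, p)
  expect_equal(H, Hs %*% p[["fusion.W_s"]] + Hg %*% p[["fusion.W_g"]] +
                 rep(1, 2) %*% p[["fusion.b"]], tolerance = 1e-12)
  # degenerate weights select one branch
  pid <- p; pid[["fusion.W_s"]] <- diag(d); pid[["fusion.W_g"]][] <- 0
  pid[["fusion.b"]][] <- 0
  expect_equal(weighted_fusion(Hs, Hg, pid), Hs, tolerance = 1e-12)
  # zero inputs give the bias row
  expect_equal(weighted_fusion(Hs * 0, Hg * 0, p)[1, ], as.numeric(p[["fusion.b"]]),
               tolerance = 1e-12)
  # linearity in the sequence argument (bias cancels in the difference)
  Hs2 <- matrix(rnorm(2 * d), 2, d)
  expect_equal(weighted_fusion(Hs + Hs2, Hg, p) - weighted_fusion(Hs2, Hg, p),
               weighted_fusion(Hs, Hg, p) - weighted_fusion(Hs * 0, Hg, p),
               tolerance = 1e-10)
  expect_error(weighted_fusion(Hs, Hg[, 1:2], p), "width")
})

test_that("the prediction head has the printed layer sizes and zero weights give probability one half", {
  cfg <- gsfl_config()
  P <- gsfl_init(cfg, dict_size = 10L)
  expect_identical(dim(P[["head.W1"]]), c(cfg$fusion_dim, 256L))
  expect_identical(dim(P[["head.W2"]]), c(256L, 64L))
  expect_identical(dim(P[["head.W3"]]), c(64L, 1L))
  n_par <- function(nms) sum(vapply(P[nms], length, integer(1)))
  expect_identical(n_par(c("head.W1", "head.b1", "head.W2", "head.b2",
                           "head.W3", "head.b3")),
                   cfg$fusion_dim * 256L + 256L + 256L * 64L + 64L + 64L + 1L)
  H <- matrix(rnorm(3 * cfg$fusion_dim), 3, cfg$fusion_dim)
  expect_identical(dim(predict_logits(H, P)), c(3L, 1L))
  P0 <- P
  for (nm in grep("^head", names(P0), value = TRUE)) P0[[nm]][] <- 0
  expect_equal(predict_logits(H, P0), matrix(0, 3, 1))
})

test_that("the contrastive loss matches hand evaluation on the orthonormal two-sample case", {
  Z <- diag(2)   # orthonormal rows; Z_s = Z_g
  loss <- contrastive_loss(Z, Z, temperature = 1)
  expect_equal(as.numeric(loss), -2, tolerance = 1e-9)
  # a common rotation of all rows preserves cosines, hence the loss
  set.seed(4)
  Zs <- matrix(rnorm(12), 3, 4); Zg <- matrix(rnorm(12), 3, 4)
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(as.numeric(contrastive_loss(Zs %*% R, Zg %*% R, 0.5)),
               as.numeric(contrastive_loss(Zs, Zg, 0.5)), tolerance = 1e-9)
  # mismatched alignment gives a positive per-sample term
  Zs2 <- rbind(c(0, 1), c(1, 0))   # row i orthogonal to Zg row i, collinear with j != i
  Zg2 <- diag(2)
  lt <- as.numeric(contrastive_loss(Zs2, Zg2, temperature = 1))
  expect_equal(lt, -2 * log(exp(0) / exp(1)), tolerance = 1e-9)
  expect_gt(lt, 0)
  expect_error(contrastive_loss(Z[1, , drop = FALSE], Z[1, , drop = FALSE], 1),
               "at least 2")
  expect_error(contrastive_loss(Z, Z, temperature = 0), "positive")
  # ntxent variant bounds the loss below by zero here
  expect_gt(as.numeric(contrastive_loss(Z, Z, 1, variant = "ntxent")), 0)
})

test_that("the contrastive loss decreases as matched cosines improve", {
  base <- diag(4)
  make_zs <- function(eps) {
    zs <- matrix(0.25, 4, 4) + eps * diag(4)
    zs
  }
  l1 <- as.numeric(contrastive_loss(make_zs(0.1), base, 0.5))
  l2 <- as.numeric(contrastive_loss(make_zs(0.8), base, 0.5))
  expect_lt(l2, l1)
})

test_that("BCE-with-logits matches closed forms and the combined loss degenerates correctly", {
  cfg <- gsfl_config(alpha = 0)
  # logit 0, label 1 -> ln 2
  expect_equal(as.numeric(bce_with_logits(matrix(0), 1)), log(2), tolerance = 1e-12)
  # saturated logits vanish
  lg <- matrix(c(20, -20), 2, 1)
  expect_lt(as.numeric(bce_with_logits(lg, c(1, 0))), 1e-6)
  # summed over samples
  lg2 <- matrix(c(0, 0, 0), 3, 1)
  expect_equal(as.numeric(bce_with_logits(lg2, c(1, 0, 1))), 3 * log(2),
               tolerance = 1e-12)
  expect_error(bce_with_logits(lg2, c(1, 2, 0)), "0/1")
  # alpha = 0 reduces the fusion loss to BCE exactly
  set.seed(5)
  Zs <- matrix(rnorm(8), 2, 4); Zg <- matrix(rnorm(8), 2, 4)
  expect_equal(as.numeric(fusion_loss(lg, c(1, 0), Zs, Zg, cfg)),
               as.numeric(bce_with_logits(lg, c(1, 0))), tolerance = 1e-12)
  cfg2 <- gsfl_config(alpha = 0.3, temperature = 0.5)
  expect_equal(as.numeric(fusion_loss(lg, c(1, 0), Zs, Zg, cfg2)),
               as.numeric(bce_with_logits(lg, c(1, 0))) +
                 0.3 * as.numeric(contrastive_loss(Zs, Zg, 0.5)),
               tolerance = 1e-12)
})

test_that("gradients reach both fusion weight matrices", {
  d <- 3L
  set.seed(6)
  params <- list(Ws = matrix(rnorm(d * d), d, d), Wg = matrix(rnorm(d * d), d, d),
                 b = matrix(rnorm(d), 1, d))
  Hs <- matrix(rnorm(2 * d), 2, d); Hg <- matrix(rnorm(2 * d), 2, d)
  got <- ad_run(function(p) {
    H <- gsfl:::op_add(gsfl:::op_add(gsfl:::op_mm(Hs, p$Ws),
                                     gsfl:::op_mm(Hg, p$Wg)), p$b)
    bce_with_logits(gsfl:::op_mm(H, matrix(1, d, 1)), c(1, 0))
  }, params)
  expect_gt(max(abs(got$grads$Ws)), 0)
  expect_gt(max(abs(got$grads$Wg)), 0)
  expect_true(all(is.finite(got$grads$Ws)))
})
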