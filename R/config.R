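# Model configuration. Defaults are the selected hyperparameter
# configuration (batch 32, learning rate 1e-4, 3 graph and 3 sequence
# layers, hidden widths 64 / 128, dropout 0.5) plus the architectural
# choices documented in the methods vignette.

#' Model configuration
#'
#' @param batch_size minibatch size
#' @param learning_rate Adam learning rate
#' @param gnn_layers message-passing iterations L
#' @param seq_layers stacked BiLSTM layers
#' @param gnn_hidden graph-branch hidden width
#' @param seq_hidden sequence-branch embedding width and per-direction LSTM
#'   width (branch output width is `2 * seq_hidden`)
#' @param dropout dropout rate (training only)
#' @param alpha contrastive-loss weight
#' @param temperature contrastive-loss temperature
#' @param epochs maximum training epochs
#' @param patience early-stopping patience (epochs without validation
#'   accuracy improvement); `Inf` disables early stopping
#' @param seed RNG seed controlling initialization, shuffling and dropout
#' @param reduction_ratio feature-attention reduction ratio r
#' @param attn_width hierarchical-attention feature width A
#' @param fusion_dim common width both branch embeddings are projected to
#'   before the affine fusion
#' @param n_heads Transformer self-attention heads
#' @param max_len maximum token-sequence length
#' @param contrastive_variant `"printed"` (denominator excludes the positive
#'   pair; may be negative) or `"ntxent"` (positive pair included)
#' @param use_fa enable atomic-level feature attention
#' @param use_ha enable hierarchical attention
#' @param use_fg_splitting multi-level tokenization (FALSE: character-level)
#' @param use_sequence_branch enable the sequence branch (FALSE: graph-only)
#' @param min_count functional-group mining threshold
#' @return a `gsfl_config` list
#' @export
gsfl_config <- function(batch_size = 32L, learning_rate = 1e-4,
                        gnn_layers = 3L, seq_layers = 3L,
                        gnn_hidden = 64L, seq_hidden = 128L,
                        dropout = 0.5, alpha = 0.1, temperature = 0.5,
                        epochs = 300L, patience = 20L, seed = 1L,
                        reduction_ratio = 4L, attn_width = 64L,
                        fusion_dim = 128L, n_heads = 4L, max_len = 128L,
                        contrastive_variant = c("printed", "ntxent"),
                        use_fa = TRUE, use_ha = TRUE,
                        use_fg_splitting = TRUE, use_sequence_branch = TRUE,
                        min_count = 5L) {
  stopifnot(batch_size >= 2L, learning_rate >= 0, gnn_layers >= 1L,
            seq_layers >= 1L, gnn_hidden > 0L, seq_hidden > 0L,
            dropout >= 0, dropout < 1, alpha >= 0, temperature > 0,
            gnn_hidden %% reduction_ratio == 0L,
            (2L * seq_hidden) %% n_heads == 0L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 gnn_layers = as.integer(gnn_layers),
                 seq_layers = as.integer(seq_layers),
                 gnn_hidden = as.integer(gnn_hidden),
                 seq_hidden = as.integer(seq_hidden),
                 dropout = dropout, alpha = alpha, temperature = temperature,
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed),
                 reduction_ratio = as.integer(reduction_ratio),
                 attn_width = as.integer(attn_width),
                 fusion_dim = as.integer(fusion_dim),
                 n_heads = as.integer(n_heads),
                 max_len = as.integer(max_len),
                 contrastive_variant = match.arg(contrastive_variant),
                 use_fa = use_fa, use_ha = use_ha,
                 use_fg_splitting = use_fg_splitting,
                 use_sequence_branch = use_sequence_branch,
                 min_count = as.integer(min_count)),
            class = "gsfl_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of every weight matrix, seeded from the
#' configuration. Parameters are a flat named list of matrices; the sequence
#' branch is omitted entirely in graph-only mode.
#'
#' @param config a `gsfl_config`
#' @param dict_size token-dictionary size (ignored when the sequence branch
#'   is disabled)
#' @return named list of parameter matrices
#' @export
gsfl_init <- function(config, dict_size = NULL) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  d <- config$gnn_hidden
  r <- config$reduction_ratio
  p <- list()
  p[["graph.W_iv"]] <- .glorot(ATOM_FDIM, d)
  p[["graph.W_ie"]] <- .glorot(BOND_FDIM, d)
  p[["graph.W_edge"]] <- .glorot(d, d)
  for (k in seq_len(config$gnn_layers)) {
    p[[sprintf("graph.comm%d.W1", k)]] <- .glorot(2L * d, d)
    p[[sprintf("graph.comm%d.b1", k)]] <- matrix(0, 1L, d)
    p[[sprintf("graph.comm%d.W2", k)]] <- .glorot(d, d)
    p[[sprintf("graph.comm%d.b2", k)]] <- matrix(0, 1L, d)
  }
  p[["graph.readout.W1"]] <- .glorot(2L * d + ATOM_FDIM, d)
  p[["graph.readout.b1"]] <- matrix(0, 1L, d)
  p[["graph.readout.W2"]] <- .glorot(d, d)
  p[["graph.readout.b2"]] <- matrix(0, 1L, d)
  if (config$use_fa) {
    p[["fa.W2"]] <- .glorot(d, d %/% r)   # squeeze d -> d/r
    p[["fa.W1"]] <- .glorot(d %/% r, d)   # excite d/r -> d
  }
  p[["pool_g.w"]] <- .glorot(d, 1L)
  p[["pool_g.b"]] <- matrix(0, 1L, 1L)

  fdim <- config$fusion_dim
  p[["fusion.P_g"]] <- .glorot(d, fdim)
  p[["fusion.W_g"]] <- .glorot(fdim, fdim)
  p[["fusion.b"]] <- matrix(0, 1L, fdim)

  if (config$use_sequence_branch) {
    stopifnot(!is.null(dict_size))
    H <- config$seq_hidden
    W <- 2L * H  # sequence-branch output width
    p[["seq.emb"]] <- .glorot(dict_size, H)
    p[["seq.level_emb"]] <- .glorot(3L, H)
    if (config$use_ha) {
      p[["ha.W1"]] <- .glorot(H, config$attn_width)
      p[["ha.b"]] <- matrix(0, 1L, config$attn_width)
      p[["ha.W2"]] <- .glorot(config$attn_width, 1L)
    }
    for (l in seq_len(config$seq_layers)) {
      nin <- if (l == 1L) H else W
      for (dir in c("f", "b")) {
        p[[sprintf("lstm%d.%s.Wx", l, dir)]] <- .glorot(nin, 4L * H)
        p[[sprintf("lstm%d.%s.Wh", l, dir)]] <- .glorot(H, 4L * H)
        p[[sprintf("lstm%d.%s.b", l, dir)]] <- matrix(0, 1L, 4L * H)
      }
    }
    p[["trans.Wq"]] <- .glorot(W, W)
    p[["trans.Wk"]] <- .glorot(W, W)
    p[["trans.Wv"]] <- .glorot(W, W)
    p[["trans.Wo"]] <- .glorot(W, W)
    p[["trans.ln1.g"]] <- matrix(1, 1L, W)
    p[["trans.ln1.b"]] <- matrix(0, 1L, W)
    p[["trans.ffn.W1"]] <- .glorot(W, 4L * W)
    p[["trans.ffn.b1"]] <- matrix(0, 1L, 4L * W)
    p[["trans.ffn.W2"]] <- .glorot(4L * W, W)
    p[["trans.ffn.b2"]] <- matrix(0, 1L, W)
    p[["trans.ln2.g"]] <- matrix(1, 1L, W)
    p[["trans.ln2.b"]] <- matrix(0, 1L, W)
    p[["pool_s.w"]] <- .glorot(W, 1L)
    p[["pool_s.b"]] <- matrix(0, 1L, 1L)
    p[["fusion.P_s"]] <- .glorot(W, fdim)
    p[["fusion.W_s"]] <- .glorot(fdim, fdim)
  }

  p[["head.W1"]] <- .glorot(fdim, 256L)
  p[["head.b1"]] <- matrix(0, 1L, 256L)
  p[["head.W2"]] <- .glorot(256L, 64L)
  p[["head.b2"]] <- matrix(0, 1L, 64L)
  p[["head.W3"]] <- .glorot(64L, 1L)
  p[["head.b3"]] <- matrix(0, 1L, 1L)
  p
}
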