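# Sequence branch: token embedding (+ level-tag embedding), hierarchical
# attention, stacked bidirectional LSTMs and a Transformer encoder block.
#
# Batched sequence tensors are stored time-major as flat matrices: the rows
# of a [B x T x H] tensor are laid out so that timestep t occupies rows
# ((t-1)*B + 1) .. (t*B). Exported single-sequence functions take [T x H]
# matrices (B = 1, where the flat layout is the matrix itself).

# Collate encoded sequences (from encode_sequence) into a flat batch,
# trimming to the longest real length in the batch.
batch_sequences <- function(encoded) {
  B <- length(encoded)
  Tmax <- max(vapply(encoded, function(e) as.integer(sum(e$mask)), integer(1)), 1L)
  idx <- t(vapply(encoded, function(e) e$indices[seq_len(Tmax)], integer(Tmax)))
  msk <- t(vapply(encoded, function(e) e$mask[seq_len(Tmax)], integer(Tmax)))
  lvl <- t(vapply(encoded, function(e) e$levels[seq_len(Tmax)], integer(Tmax)))
  if (Tmax == 1L) { idx <- matrix(idx, B); msk <- matrix(msk, B); lvl <- matrix(lvl, B) }
  list(indices = idx, mask = msk, levels = lvl, B = B, Tlen = Tmax,
       flat_idx = as.vector(idx), flat_mask = matrix(as.vector(msk), ncol = 1L),
       flat_lvl = as.vector(lvl),
       sample_id = rep(seq_len(B), Tmax))
}

.embed_batch <- function(sbatch, P) {
  eidx <- ifelse(sbatch$flat_mask[, 1L] > 0, sbatch$flat_idx + 1L, 0L)
  X <- op_gather(P[["seq.emb"]], eidx)
  op_add(X, op_gather(P[["seq.level_emb"]], sbatch$flat_lvl))
}

.ha_batch <- function(X, sbatch, P) {
  Z <- op_tanh(op_add(op_mm(X, P[["ha.W1"]]), P[["ha.b"]]))
  s <- op_mm(Z, P[["ha.W2"]])
  w <- seg_softmax(s, sbatch$sample_id, sbatch$B, sbatch$flat_mask)
  X_att <- op_mul(X, w)
  h_att <- op_rowsum(X_att, sbatch$sample_id, sbatch$B)
  hp <- op_gather(h_att, sbatch$sample_id)       # expand along T
  list(weights = w, X_atten = X_att, h_atten = h_att, expanded = hp)
}

.lstm_dir <- function(I, sbatch, P, layer, dir, H) {
  pre <- sprintf("lstm%d.%s", layer, dir)
  XW <- op_add(op_mm(I, P[[paste0(pre, ".Wx")]]), P[[paste0(pre, ".b")]])
  op_lstm_dir(XW, P[[paste0(pre, ".Wh")]], sbatch$mask,
              sbatch$B, sbatch$Tlen, H, reverse = (dir == "b"))
}

.bilstm_batch <- function(I, sbatch, P, config, drop = .no_drop) {
  H <- config$seq_hidden
  for (l in seq_len(config$seq_layers)) {
    I <- op_cbind(list(.lstm_dir(I, sbatch, P, l, "f", H),
                       .lstm_dir(I, sbatch, P, l, "b", H)))
    if (l < config$seq_layers) I <- drop(I)
  }
  op_mul(I, sbatch$flat_mask)
}

.transformer_batch <- function(S, sbatch, P, config, drop = .no_drop) {
  B <- sbatch$B; Tlen <- sbatch$Tlen
  W <- ncol(ad_value(S))
  nh <- config$n_heads
  dk <- W %/% nh
  Q <- op_mm(S, P[["trans.Wq"]])
  K <- op_mm(S, P[["trans.Wk"]])
  V <- op_mm(S, P[["trans.Wv"]])
  attn <- op_mha(Q, K, V, sbatch$mask, B, Tlen, nh, 1 / sqrt(dk))
  A1 <- op_layernorm(op_add(S, drop(op_mm(attn, P[["trans.Wo"]]))),
                     P[["trans.ln1.g"]], P[["trans.ln1.b"]])
  FF <- op_add(op_mm(drop(op_relu(op_add(op_mm(A1, P[["trans.ffn.W1"]]),
                                         P[["trans.ffn.b1"]]))),
                     P[["trans.ffn.W2"]]), P[["trans.ffn.b2"]])
  out <- op_layernorm(op_add(A1, FF), P[["trans.ln2.g"]], P[["trans.ln2.b"]])
  op_mul(out, sbatch$flat_mask)
}

.seq_branch <- function(sbatch, P, config, drop = .no_drop) {
  X <- .embed_batch(sbatch, P)
  I <- if (isTRUE(config$use_ha)) {
    ha <- .ha_batch(X, sbatch, P)
    op_mul(op_add(ha$X_atten, ha$expanded), sbatch$flat_mask)
  } else X
  S <- .bilstm_batch(I, sbatch, P, config, drop)
  .transformer_batch(S, sbatch, P, config, drop)
}

# -- exported single-sequence surface ----------------------------------------

.single_sbatch <- function(Tlen, mask) {
  list(B = 1L, Tlen = Tlen, mask = matrix(mask, 1L),
       flat_mask = matrix(mask, ncol = 1L), sample_id = rep(1L, Tlen))
}

#' Embed an encoded token sequence
#'
#' Looks up token embeddings (rows of `seq.emb`; 0-based dictionary indices)
#' and adds the learned 3-way level-tag embedding. Padded positions are zero
#' vectors.
#'
#' @param indices 0-based dictionary indices (length T)
#' @param mask 0/1 vector of real positions
#' @param levels integer level tags (1 functional group, 2 ion group,
#'   3 atom, 0 pad)
#' @param params parameter list with `seq.emb` and `seq.level_emb`
#' @return matrix T x H
#' @export
embed_tokens <- function(indices, mask, levels, params) {
  if (any(indices[mask > 0] + 1L > nrow(ad_value(params[["seq.emb"]]))) ||
      any(indices < 0L))
    stop("token index outside dictionary range")
  sb <- list(flat_idx = indices, flat_mask = matrix(mask, ncol = 1L),
             flat_lvl = levels)
  .embed_batch(sb, params)
}

#' Hierarchical attention over a token sequence
#'
#' Scores every position through `Z = tanh(X W1 + b)`, `s = Z W2`, takes a
#' masked softmax over positions, reweights the input (`X_atten = X * S`),
#' pools it (`h_atten = sum_t X_atten`) and broadcasts the pooled vector
#' back along the sequence.
#'
#' @param X matrix T x H of embedded tokens
#' @param mask 0/1 vector of length T (at least one position unmasked)
#' @param params parameter list with `ha.W1` (H x A), `ha.b` (1 x A),
#'   `ha.W2` (A x 1)
#' @return list with `weights` (T x 1, summing to 1 over unmasked
#'   positions), `X_atten`, `h_atten` (1 x H), `expanded` (T x H)
#' @export
hierarchical_attention <- function(X, mask, params) {
  if (sum(mask) == 0L) stop("fully masked sequence")
  Tlen <- nrow(ad_value(X))
  sb <- .single_sbatch(Tlen, mask)
  .ha_batch(X, sb, params)
}

#' BiLSTM encoding of one sequence
#'
#' Runs the stacked bidirectional LSTM over the unmasked positions and
#' concatenates forward and backward hidden states per position.
#'
#' @param X matrix T x H_in
#' @param mask 0/1 vector of length T
#' @param params parameter list with `lstm<l>.<f|b>.{Wx,Wh,b}` matrices
#' @param config a `gsfl_config` (uses `seq_layers`, `seq_hidden`)
#' @return matrix T x (2 * seq_hidden)
#' @export
bilstm_encode <- function(X, mask, params, config) {
  if (nrow(ad_value(X)) == 0L) stop("zero-length sequence")
  sb <- .single_sbatch(nrow(ad_value(X)), mask)
  .bilstm_batch(X, sb, params, config)
}

#' Transformer self-attention encoding of one sequence
#'
#' A standard encoder block (multi-head self-attention, feed-forward,
#' residual connections, layer normalization) with padded positions masked
#' out of the attention; shape-preserving.
#'
#' @param X matrix T x W (W divisible by `config$n_heads`)
#' @param mask 0/1 vector of length T
#' @param params parameter list with the `trans.*` matrices
#' @param config a `gsfl_config`
#' @return matrix T x W
#' @export
transformer_encode <- function(X, mask, params, config) {
  sb <- .single_sbatch(nrow(ad_value(X)), mask)
  .transformer_batch(X, sb, params, config)
}
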