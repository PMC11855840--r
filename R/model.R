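# Full model: branch encoders -> global attention pooling -> projection to
# the fusion width -> affine fusion -> prediction head.

# Forward pass over a prepared batch. Returns logits plus the projected
# branch embeddings used by the contrastive term.
gsfl_forward <- function(P, gbatch, sbatch, config, drop = .no_drop) {
  h_v <- .graph_branch(gbatch, P, config, drop)
  Hg_pool <- .pool_batch(h_v, gbatch$graph_id, gbatch$n_graphs,
                         matrix(1, gbatch$n_atoms, 1L), P, "pool_g")
  Hg <- op_mm(Hg_pool, P[["fusion.P_g"]])
  Hs <- NULL
  if (isTRUE(config$use_sequence_branch)) {
    tok <- .seq_branch(sbatch, P, config, drop)
    Hs_pool <- .pool_batch(tok, sbatch$sample_id, sbatch$B,
                           sbatch$flat_mask, P, "pool_s")
    Hs <- op_mm(Hs_pool, P[["fusion.P_s"]])
  }
  H <- weighted_fusion(Hs, Hg, P)
  logits <- predict_logits(H, P, drop)
  list(logits = logits, Z_s = Hs, Z_g = Hg)
}

# Tokenization + encoding pipeline shared by train/predict.
.prepare_sequences <- function(smiles, vocab, dict, config) {
  tokfun <- if (isTRUE(config$use_fg_splitting))
    function(s) tokenize_smiles(s, vocab) else tokenize_chars
  seqs <- lapply(smiles, tokfun)
  lapply(seqs, encode_sequence, dict = dict, max_len = config$max_len)
}

# Plain-matrix (evaluation-mode) scores for a record data.frame.
.model_scores <- function(P, records, vocab, dict, config, chunk = 256L) {
  graphs <- build_mol_graphs(records$smiles)
  out <- numeric(nrow(records))
  for (start in seq(1L, nrow(records), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(records))
    gbatch <- batch_graphs(graphs[ii])
    sbatch <- if (isTRUE(config$use_sequence_branch))
      batch_sequences(.prepare_sequences(records$smiles[ii], vocab, dict, config))
    fw <- gsfl_forward(P, gbatch, sbatch, config)
    out[ii] <- 1 / (1 + exp(-as.numeric(ad_value(fw$logits))))
  }
  out
}
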