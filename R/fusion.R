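# Fusion of the two branch embeddings, the prediction head, and the
# training losses (binary cross-entropy + cross-modal contrastive term).

.pool_batch <- function(items, group, ngroups, mask, P, prefix) {
  s <- op_add(op_mm(items, P[[paste0(prefix, ".w")]]), P[[paste0(prefix, ".b")]])
  w <- seg_softmax(s, group, ngroups, mask)
  op_rowsum(op_mul(items, w), group, ngroups)
}

#' Global attention pooling
#'
#' Scores each item vector with a learned gate (linear map to a scalar),
#' softmaxes the scores over the set, and returns the weighted sum. Used to
#' pool atom vectors (graph branch) and token vectors (sequence branch) into
#' molecule-level embeddings.
#'
#' @param items matrix n x d of item vectors
#' @param mask 0/1 vector of length n (NULL for all real)
#' @param gate_w d x 1 gate weight; `gate_b` 1 x 1 gate bias
#' @param gate_b see `gate_w`
#' @return 1 x d pooled vector
#' @export
global_attention_pool <- function(items, mask = NULL, gate_w, gate_b = matrix(0, 1, 1)) {
  n <- nrow(ad_value(items))
  if (n == 0L || (!is.null(mask) && sum(mask) == 0L)) stop("empty set to pool")
  if (is.null(mask)) mask <- rep(1, n)
  P <- list(pool.w = gate_w, pool.b = gate_b)
  .pool_batch(items, rep(1L, n), 1L, matrix(mask, ncol = 1L), P, "pool")
}

#' Affine weighted fusion of branch embeddings
#'
#' `H = H_s W_s + H_g W_g + b` on the common fusion width.
#'
#' @param H_s,H_g batch x fusion_dim branch embeddings (either may be NULL
#'   in single-branch ablations)
#' @param params list with `fusion.W_s`, `fusion.W_g`, `fusion.b`
#' @return batch x fusion_dim fused representation
#' @export
weighted_fusion <- function(H_s, H_g, params) {
  if (!is.null(H_s) && !is.null(H_g) &&
      ncol(ad_value(H_s)) != ncol(ad_value(H_g)))
    stop("H_s and H_g widths differ; project to the fusion width first")
  out <- NULL
  if (!is.null(H_s)) out <- op_mm(H_s, params[["fusion.W_s"]])
  if (!is.null(H_g)) {
    hg <- op_mm(H_g, params[["fusion.W_g"]])
    out <- if (is.null(out)) hg else op_add(out, hg)
  }
  op_add(out, params[["fusion.b"]])
}

#' Prediction head
#'
#' Three-layer MLP `fusion_dim -> 256 -> 64 -> 1` (ReLU + dropout after the
#' first layer, ReLU after the second), returning one pre-sigmoid logit per
#' molecule.
#'
#' @param H batch x fusion_dim fused representations
#' @param params list with `head.W1..W3`, `head.b1..b3`
#' @param drop dropout closure (identity at evaluation)
#' @return batch x 1 logits
#' @export
predict_logits <- function(H, params, drop = .no_drop) {
  h1 <- drop(op_relu(op_add(op_mm(H, params[["head.W1"]]), params[["head.b1"]])))
  h2 <- op_relu(op_add(op_mm(h1, params[["head.W2"]]), params[["head.b2"]]))
  op_add(op_mm(h2, params[["head.W3"]]), params[["head.b3"]])
}

#' Cross-modal contrastive loss
#'
#' For each anchor modality, matched graph/sequence pairs are pulled
#' together relative to mismatched pairs using temperature-scaled cosine
#' similarities. In the default `"printed"` variant the denominator excludes
#' the positive pair, so the loss is unbounded below and can be negative;
#' `"ntxent"` includes the positive pair (standard normalized
#' temperature-scaled cross-entropy, non-negative).
#'
#' @param Z_s,Z_g N x d embedding matrices (rows are L2-normalized
#'   internally)
#' @param temperature positive temperature
#' @param variant `"printed"` or `"ntxent"`
#' @return scalar (1 x 1) loss, summed over both anchor directions
#' @export
contrastive_loss <- function(Z_s, Z_g, temperature = 0.5,
                             variant = c("printed", "ntxent")) {
  variant <- match.arg(variant)
  N <- nrow(ad_value(Z_s))
  if (N < 2L) stop("contrastive loss needs at least 2 samples")
  if (temperature <= 0) stop("temperature must be positive")
  Zs <- l2_normalize_rows(Z_s)
  Zg <- l2_normalize_rows(Z_g)
  E <- op_exp(op_scale(op_mmt(Zs, Zg), 1 / temperature))   # E_ij = exp(cos(s_i, g_j)/T)
  I <- diag(N)
  ones <- matrix(1, N, 1L)
  num_s <- op_mm(op_mul(E, I), ones)                        # diagonal terms
  den_off_s <- op_mm(op_mul(E, 1 - I), ones)                # j != i
  den_s <- if (variant == "printed") den_off_s else op_add(den_off_s, num_s)
  term_s <- op_scale(op_sum(op_sub(op_log(den_s), op_log(num_s))), 1 / N)
  # anchor swapped: sequence rows against all graph anchors = transpose of E
  num_g <- num_s
  den_off_g <- .col_sums_offdiag(E, I, N)
  den_g <- if (variant == "printed") den_off_g else op_add(den_off_g, num_g)
  term_g <- op_scale(op_sum(op_sub(op_log(den_g), op_log(num_g))), 1 / N)
  op_add(term_s, term_g)
}

.col_sums_offdiag <- function(E, I, N) {
  # column sums of the off-diagonal entries, as an N x 1 column
  op_mm(.transpose_ad(op_mul(E, 1 - I)), matrix(1, N, 1L))
}

.transpose_ad <- function(a) {
  if (!ad_is(a)) return(t(a))
  .unop(a, function(x) t(x), function(g, x, v) t(g))
}

#' Binary cross-entropy with logits
#'
#' Numerically stable `sum_i [softplus(logit_i) - label_i * logit_i]`
#' (summed, not averaged, over the batch).
#'
#' @param logits batch x 1 pre-sigmoid outputs
#' @param labels 0/1 vector
#' @return scalar (1 x 1) loss
#' @export
bce_with_logits <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  lab <- matrix(as.numeric(labels), ncol = 1L)
  op_sum(op_sub(op_softplus(logits), op_mul(lab, logits)))
}

#' Combined fusion loss
#'
#' `L = L_BCE + alpha * L_Contrast`. With `alpha = 0` (or in graph-only
#' mode, where no second modality exists) this is exactly the summed binary
#' cross-entropy.
#'
#' @param logits batch x 1 logits
#' @param labels 0/1 vector
#' @param Z_s,Z_g branch embeddings for the contrastive term (may be NULL)
#' @param config a `gsfl_config` (uses `alpha`, `temperature`,
#'   `contrastive_variant`)
#' @return scalar (1 x 1) loss
#' @export
fusion_loss <- function(logits, labels, Z_s = NULL, Z_g = NULL, config) {
  loss <- bce_with_logits(logits, labels)
  if (config$alpha > 0 && !is.null(Z_s) && !is.null(Z_g) &&
      nrow(ad_value(Z_s)) >= 2L) {
    loss <- op_add(loss, op_scale(contrastive_loss(Z_s, Z_g, config$temperature,
                                                   config$contrastive_variant),
                                  config$alpha))
  }
  loss
}
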