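# Graph branch: iterative directed-edge message passing over the molecular
# graph followed by channel-wise feature attention.
#
# All functions are written against the generic op layer, so they run
# tape-free on plain matrices (inference, unit testing) and tracked during
# training. Batches concatenate the atoms/edges of several molecules with a
# per-atom graph id.

# Collate a list of mol_graph into one batch: global atom indexing, directed
# edges, and a gather table of incoming directed edges per atom (0 = pad).
batch_graphs <- function(graphs) {
  n_at <- vapply(graphs, `[[`, integer(1), "n_atoms")
  offs <- cumsum(c(0L, utils::head(n_at, -1L)))
  X_v <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  X_e <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (g$n_bonds == 0L) matrix(0, 0L, BOND_FDIM) else
      g$bond_features[g$edge_bond, , drop = FALSE]
  }))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges + offs[i]))
  if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
  A <- sum(n_at)
  graph_id <- rep(seq_along(graphs), n_at)
  # incoming directed edges per atom
  tgt <- if (nrow(edges)) edges[, 2L] else integer(0)
  indeg <- tabulate(tgt, nbins = A)
  K <- max(1L, if (length(indeg)) max(indeg) else 0L)
  gidx <- matrix(0L, A, K)
  slot <- integer(A)
  for (e in seq_along(tgt)) {
    a <- tgt[e]; slot[a] <- slot[a] + 1L
    gidx[a, slot[a]] <- e
  }
  # atom gather table per graph (for segment max in feature attention)
  Kat <- max(n_at)
  aidx <- matrix(0L, length(graphs), Kat)
  for (i in seq_along(graphs)) aidx[i, seq_len(n_at[i])] <- offs[i] + seq_len(n_at[i])
  list(X_v = X_v, X_e = X_e, edges = edges, graph_id = graph_id,
       n_graphs = length(graphs), n_atoms = A, gidx = gidx, aidx = aidx,
       cache = new.env(parent = emptyenv()))
}

# segment max via gathered candidates; pad slots are pushed to -1e30 so they
# never win, then unselected (gradient-free). Penalty matrices are cached in
# the batch's environment (keyed by slot name and width) because the same
# batch runs the aggregation once per message-passing layer.
.seg_max <- function(x, idx_mat, cache = NULL, slot = "") {
  d <- ncol(ad_value(x))
  key <- paste0(slot, d)
  pen <- if (!is.null(cache)) cache[[key]]
  if (is.null(pen)) {
    pen <- lapply(seq_len(ncol(idx_mat)), function(k)
      matrix(ifelse(idx_mat[, k] > 0L, 0, -1e30), nrow(idx_mat), d))
    if (!is.null(cache)) cache[[key]] <- pen
  }
  out <- op_add(op_gather(x, idx_mat[, 1L]), pen[[1L]])
  for (k in seq_len(ncol(idx_mat))[-1L])
    out <- op_max2(out, op_add(op_gather(x, idx_mat[, k]), pen[[k]]))
  out
}

# AGGREGATE: sum of incoming directed-edge states, element-wise multiplied
# by their element-wise maximum (the message enhancer); atoms without
# incoming edges produce zero messages.
.aggregate_edges <- function(h_e, batch) {
  if (nrow(batch$edges) == 0L)
    return(matrix(0, batch$n_atoms, ncol(ad_value(h_e))))
  s <- op_rowsum(h_e, batch$edges[, 2L], batch$n_atoms)
  zero <- if (!is.null(batch$cache)) {
    z <- batch$cache[[paste0("zero", ncol(ad_value(h_e)))]]
    if (is.null(z)) {
      z <- matrix(0, batch$n_atoms, ncol(ad_value(h_e)))
      batch$cache[[paste0("zero", ncol(ad_value(h_e)))]] <- z
    }
    z
  } else matrix(0, batch$n_atoms, ncol(ad_value(h_e)))
  m <- op_max2(.seg_max(h_e, batch$gidx, batch$cache, "gidx"), zero)
  op_mul(s, m)
}

# COMMUNICATE: one-hidden-layer MLP on the concatenated inputs
.communicate <- function(inputs, P, prefix, drop) {
  h <- op_relu(op_add(op_mm(op_cbind(inputs), P[[paste0(prefix, ".W1")]]),
                      P[[paste0(prefix, ".b1")]]))
  op_add(op_mm(drop(h), P[[paste0(prefix, ".W2")]]), P[[paste0(prefix, ".b2")]])
}

.no_drop <- function(x) x

.graph_branch <- function(batch, P, config, drop = .no_drop) {
  h_v0 <- op_relu(op_mm(batch$X_v, P[["graph.W_iv"]]))
  h_e0 <- if (nrow(batch$X_e)) op_relu(op_mm(batch$X_e, P[["graph.W_ie"]])) else
    matrix(0, 0L, config$gnn_hidden)
  h_v <- h_v0; h_e <- h_e0
  src <- batch$edges[, 1L]
  for (k in seq_len(config$gnn_layers)) {
    m <- .aggregate_edges(h_e, batch)
    h_v <- .communicate(list(m, h_v), P, sprintf("graph.comm%d", k), drop)
    if (nrow(batch$edges))
      h_e <- op_relu(op_add(h_e0, op_mm(op_sub(op_gather(h_v, src), h_e),
                                        P[["graph.W_edge"]])))
  }
  m <- .aggregate_edges(h_e, batch)
  h_v <- .communicate(list(m, h_v, batch$X_v), P, "graph.readout", drop)
  if (isTRUE(config$use_fa)) h_v <- .feature_attention_batch(h_v, batch, P)
  h_v
}

.feature_attention_batch <- function(h_v, batch, P) {
  g_sum <- op_rowsum(h_v, batch$graph_id, batch$n_graphs)
  g_max <- .seg_max(h_v, batch$aidx, batch$cache, "aidx")
  z <- op_add(op_relu(op_mm(g_sum, P[["fa.W2"]])),
              op_relu(op_mm(g_max, P[["fa.W2"]])))
  c_w <- op_sigmoid(op_mm(z, P[["fa.W1"]]))
  op_mul(h_v, op_gather(c_w, batch$graph_id))
}

# -- exported single-molecule surface ----------------------------------------

#' Initialize hidden states for a molecular graph
#'
#' Linear projections of the atom and (directed) bond feature matrices into
#' the hidden space, followed by ReLU. Bond features are duplicated onto
#' both directed edges.
#'
#' @param graph a `mol_graph`
#' @param params parameter list containing `graph.W_iv` (133 x d) and
#'   `graph.W_ie` (14 x d)
#' @return list with `h_v` (n_atoms x d) and `h_e` (2*n_bonds x d)
#' @export
graph_init_hidden <- function(graph, params) {
  d <- ncol(params[["graph.W_iv"]])
  X_e <- if (graph$n_bonds) graph$bond_features[graph$edge_bond, , drop = FALSE] else
    matrix(0, 0L, BOND_FDIM)
  list(h_v = op_relu(op_mm(graph$atom_features, params[["graph.W_iv"]])),
       h_e = if (nrow(X_e)) op_relu(op_mm(X_e, params[["graph.W_ie"]])) else
         matrix(0, 0L, d))
}

#' One message-passing iteration
#'
#' Aggregates incoming directed-edge states per atom (sum times element-wise
#' maximum), updates atom states through the layer's communicate MLP, and
#' refreshes edge states from their source atoms:
#' `h_e <- ReLU(h_e0 + (h_v[src] - h_e) W)`.
#'
#' @param state list with `h_v`, `h_e` (and `h_e0`, defaulting to the given
#'   `h_e` on the first call)
#' @param graph a `mol_graph`
#' @param params parameter list (see [gsfl_init()])
#' @param k layer index selecting the communicate MLP
#' @return updated state list with `h_v`, `h_e`, `h_e0`, `m_v`
#' @export
message_pass_step <- function(state, graph, params, k = 1L) {
  batch <- batch_graphs(list(graph))
  h_e0 <- if (is.null(state$h_e0)) state$h_e else state$h_e0
  m <- .aggregate_edges(state$h_e, batch)
  h_v <- .communicate(list(m, state$h_v), params, sprintf("graph.comm%d", k), .no_drop)
  h_e <- state$h_e
  if (nrow(batch$edges))
    h_e <- op_relu(op_add(h_e0, op_mm(op_sub(op_gather(h_v, batch$edges[, 1L]), state$h_e),
                                      params[["graph.W_edge"]])))
  list(h_v = h_v, h_e = h_e, h_e0 = h_e0, m_v = m)
}

#' Final readout of per-atom representations
#'
#' Aggregates the final edge states and passes the message, the last atom
#' state and the raw atom features through the readout MLP.
#'
#' @inheritParams message_pass_step
#' @return matrix n_atoms x d of final per-atom vectors
#' @export
readout_nodes <- function(state, graph, params) {
  batch <- batch_graphs(list(graph))
  m <- .aggregate_edges(state$h_e, batch)
  .communicate(list(m, state$h_v, graph$atom_features), params, "graph.readout", .no_drop)
}

#' Atomic-level feature attention
#'
#' Pools the molecule's atom vectors by sum and element-wise max, passes both
#' through a shared squeeze-excite operator
#' `c = sigmoid((ReLU(g_sum W2) + ReLU(g_max W2)) W1)` and reweights every
#' atom vector channel-wise by `c`.
#'
#' @param h matrix n_atoms x d of atom hidden vectors (n_atoms >= 1)
#' @param params parameter list with `fa.W1` (d/r x d) and `fa.W2` (d x d/r)
#' @return matrix of the same shape, `h * c`
#' @export
feature_attention <- function(h, params) {
  if (nrow(ad_value(h)) == 0L) stop("feature attention needs at least one atom")
  n <- nrow(ad_value(h))
  batch <- list(graph_id = rep(1L, n), n_graphs = 1L,
                aidx = matrix(seq_len(n), 1L))
  .feature_attention_batch(h, batch, params)
}
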