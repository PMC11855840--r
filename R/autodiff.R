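# Tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every op accepts plain matrices and/or tracked values ("adv"). With no
# tracked argument it computes eagerly and returns a matrix, so the same
# forward code serves both inference (fast, tape-free) and training.
# Tracked values are created by ad_param() against an active tape; backward
# traverses the tape in reverse, accumulating gradients per node.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_is <- function(x) inherits(x, "adv")

ad_value <- function(x) if (ad_is(x)) x$v else x

.ad_push <- function(tape, value, parents, backward) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- list(parents = parents, backward = backward)
  tape$n <- n
  structure(list(id = n, v = value, tape = tape), class = "adv")
}

#' Create a tracked parameter on a tape
#'
#' @param tape a tape from `new_tape()`
#' @param value numeric matrix
#' @keywords internal
ad_param <- function(tape, value) .ad_push(tape, value, integer(0), NULL)

# Run backward from a scalar (1x1) node; returns list of gradients indexed by
# node id (only ids reachable from `root` are populated).
ad_backward <- function(root) {
  stopifnot(ad_is(root), length(root$v) == 1L)
  tape <- root$tape
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (p == 0L || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# -- op helpers ---------------------------------------------------------------

.pid <- function(x) if (ad_is(x)) x$id else 0L

.binop <- function(a, b, fwd, bwd_a, bwd_b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- fwd(av, bv)
  if (!ad_is(a) && !ad_is(b)) return(v)
  tape <- if (ad_is(a)) a$tape else b$tape
  .ad_push(tape, v, c(.pid(a), .pid(b)), function(g) {
    list(if (ad_is(a)) bwd_a(g, av, bv, v) else NULL,
         if (ad_is(b)) bwd_b(g, av, bv, v) else NULL)
  })
}

.unop <- function(a, fwd, bwd) {
  av <- ad_value(a)
  v <- fwd(av)
  if (!ad_is(a)) return(v)
  .ad_push(a$tape, v, .pid(a), function(g) list(bwd(g, av, v)))
}

# -- arithmetic ---------------------------------------------------------------

op_mm <- function(a, b) .binop(a, b, function(x, y) x %*% y,
  function(g, x, y, v) g %*% t(y),
  function(g, x, y, v) t(x) %*% g)

# a %*% t(b)
op_mmt <- function(a, b) .binop(a, b, function(x, y) tcrossprod(x, y),
  function(g, x, y, v) g %*% y,
  function(g, x, y, v) crossprod(g, x))

# b may be a 1 x ncol(a) row bias (recycled over rows) or same shape as a
op_add <- function(a, b) {
  bias <- nrow(as.matrix(ad_value(b))) == 1L && nrow(as.matrix(ad_value(a))) > 1L
  .binop(a, b,
    function(x, y) if (bias) sweep(x, 2L, as.numeric(y), "+") else x + y,
    function(g, x, y, v) g,
    function(g, x, y, v) if (bias) matrix(colSums(g), 1L) else g)
}

op_sub <- function(a, b) .binop(a, b, function(x, y) x - y,
  function(g, x, y, v) g,
  function(g, x, y, v) -g)

# elementwise; b may be an n x 1 column (recycled across columns) or same shape
op_mul <- function(a, b) {
  col <- ncol(as.matrix(ad_value(b))) == 1L && ncol(as.matrix(ad_value(a))) > 1L
  .binop(a, b,
    function(x, y) if (col) x * as.numeric(y) else x * y,
    function(g, x, y, v) if (col) g * as.numeric(y) else g * y,
    function(g, x, y, v) if (col) matrix(rowSums(g * x), ncol = 1L) else g * x)
}

op_div <- function(a, b) {
  col <- ncol(as.matrix(ad_value(b))) == 1L && ncol(as.matrix(ad_value(a))) > 1L
  .binop(a, b,
    function(x, y) if (col) x / as.numeric(y) else x / y,
    function(g, x, y, v) if (col) g / as.numeric(y) else g / y,
    function(g, x, y, v) {
      q <- if (col) matrix(-rowSums(g * x) / as.numeric(y)^2, ncol = 1L) else -g * x / y^2
      q
    })
}

op_scale <- function(a, s) .unop(a, function(x) x * s, function(g, x, v) g * s)

op_max2 <- function(a, b) .binop(a, b, function(x, y) pmax(x, y),
  function(g, x, y, v) g * (x >= y),
  function(g, x, y, v) g * (x < y))

# -- nonlinearities -----------------------------------------------------------

op_relu     <- function(a) .unop(a, function(x) x * (x > 0), function(g, x, v) g * (x > 0))
op_sigmoid  <- function(a) .unop(a, function(x) 1 / (1 + exp(-x)), function(g, x, v) g * v * (1 - v))
op_tanh     <- function(a) .unop(a, function(x) tanh(x), function(g, x, v) g * (1 - v^2))
op_exp      <- function(a) .unop(a, function(x) exp(x), function(g, x, v) g * v)
op_log      <- function(a) .unop(a, function(x) log(x), function(g, x, v) g / x)
op_sqrt     <- function(a) .unop(a, function(x) sqrt(x), function(g, x, v) g / (2 * v))
op_softplus <- function(a) .unop(a,
  function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
  function(g, x, v) g / (1 + exp(-x)))

# -- reductions / structure ---------------------------------------------------

op_sum <- function(a) .unop(a, function(x) matrix(sum(x), 1L, 1L),
  function(g, x, v) matrix(as.numeric(g), nrow(x), ncol(x)))

op_mean <- function(a) {
  n <- length(ad_value(a))
  op_scale(op_sum(a), 1 / n)
}

# gather rows by index; idx == 0 yields a zero row
op_gather <- function(a, idx) {
  av <- ad_value(a)
  d <- ncol(av)
  fwd <- function(x) {
    out <- matrix(0, length(idx), d)
    nz <- idx > 0L
    out[nz, ] <- x[idx[nz], , drop = FALSE]
    out
  }
  if (!ad_is(a)) return(fwd(av))
  .unop(a, fwd, function(g, x, v) .scatter_add(g, idx, nrow(x)))
}

.scatter_add <- function(g, idx, n) {
  keep <- idx > 0L
  if (!any(keep)) return(matrix(0, n, ncol(g)))
  rs <- rowsum(g[keep, , drop = FALSE], group = idx[keep])
  out <- matrix(0, n, ncol(g))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# segment (group-wise) row sums -> ngroups x d; group in 1..ngroups
op_rowsum <- function(a, group, ngroups) {
  fwd <- function(x) {
    rs <- rowsum(x, group = group)
    out <- matrix(0, ngroups, ncol(x))
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  if (!ad_is(a)) return(fwd(ad_value(a)))
  .unop(a, fwd, function(g, x, v) g[group, , drop = FALSE])
}

op_rbind <- function(lst) {
  vals <- lapply(lst, ad_value)
  v <- do.call(rbind, vals)
  tracked <- vapply(lst, ad_is, logical(1))
  if (!any(tracked)) return(v)
  tape <- lst[[which(tracked)[1]]]$tape
  rows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(rows); starts <- ends - rows + 1L
  .ad_push(tape, v, vapply(lst, .pid, integer(1)), function(g) {
    lapply(seq_along(lst), function(k)
      if (tracked[k]) g[starts[k]:ends[k], , drop = FALSE] else NULL)
  })
}

op_cbind <- function(lst) {
  vals <- lapply(lst, ad_value)
  v <- do.call(cbind, vals)
  tracked <- vapply(lst, ad_is, logical(1))
  if (!any(tracked)) return(v)
  tape <- lst[[which(tracked)[1]]]$tape
  cols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(cols); starts <- ends - cols + 1L
  .ad_push(tape, v, vapply(lst, .pid, integer(1)), function(g) {
    lapply(seq_along(lst), function(k)
      if (tracked[k]) g[, starts[k]:ends[k], drop = FALSE] else NULL)
  })
}

op_rows <- function(a, from, to) {
  fwd <- function(x) x[from:to, , drop = FALSE]
  if (!ad_is(a)) return(fwd(ad_value(a)))
  n <- nrow(ad_value(a))
  .unop(a, fwd, function(g, x, v) {
    out <- matrix(0, n, ncol(x)); out[from:to, ] <- g; out
  })
}

op_cols <- function(a, from, to) {
  fwd <- function(x) x[, from:to, drop = FALSE]
  if (!ad_is(a)) return(fwd(ad_value(a)))
  .unop(a, fwd, function(g, x, v) {
    out <- matrix(0, nrow(x), ncol(x)); out[, from:to] <- g; out
  })
}

# row-wise softmax (used for T x T self-attention score matrices)
op_softmax_rows <- function(a) {
  fwd <- function(x) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  }
  if (!ad_is(a)) return(fwd(ad_value(a)))
  .unop(a, fwd, function(g, x, v) v * (g - rowSums(g * v)))
}

# per-row layer normalization with learnable gain/offset (1 x d each)
op_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_value(a); gv <- ad_value(gamma); bv <- ad_value(beta)
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowSums(xc^2) / d
  sd_ <- sqrt(va + eps)
  xn <- xc / sd_
  v <- sweep(sweep(xn, 2L, as.numeric(gv), "*"), 2L, as.numeric(bv), "+")
  if (!ad_is(a) && !ad_is(gamma) && !ad_is(beta)) return(v)
  tape <- if (ad_is(a)) a$tape else if (ad_is(gamma)) gamma$tape else beta$tape
  .ad_push(tape, v, c(.pid(a), .pid(gamma), .pid(beta)), function(g) {
    gxn <- sweep(g, 2L, as.numeric(gv), "*")
    # d xn / d x backward for per-row standardization
    ga <- (gxn - rowMeans(gxn) - xn * rowMeans(gxn * xn)) / sd_
    list(if (ad_is(a)) ga else NULL,
         if (ad_is(gamma)) matrix(colSums(g * xn), 1L) else NULL,
         if (ad_is(beta)) matrix(colSums(g), 1L) else NULL)
  })
}

# Fused one-direction LSTM over a whole (flat, time-major) batch.
# XW: n x 4H precomputed input projections (n = Tlen * B, timestep t in rows
# (t-1)*B+1 .. t*B); Wh: H x 4H recurrent weights; mask: B x Tlen. Gate
# order i|f|o|g. Returns the flat n x H hidden-state sequence (post mask
# carry-through). One tape node; backward is hand-rolled BPTT.
op_lstm_dir <- function(XW, Wh, mask, B, Tlen, H, reverse = FALSE) {
  XWv <- ad_value(XW); Whv <- ad_value(Wh)
  steps <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  st <- vector("list", Tlen)  # per-step activations for BPTT
  out <- matrix(0, nrow(XWv), H)
  for (t in steps) {
    rows <- (t - 1L) * B + seq_len(B)
    G <- XWv[rows, , drop = FALSE] + h %*% Whv
    i <- 1 / (1 + exp(-G[, 1:H, drop = FALSE]))
    f <- 1 / (1 + exp(-G[, H + 1:H, drop = FALSE]))
    o <- 1 / (1 + exp(-G[, 2 * H + 1:H, drop = FALSE]))
    g <- tanh(G[, 3 * H + 1:H, drop = FALSE])
    ctil <- f * cc + i * g
    tc <- tanh(ctil)
    m <- mask[, t]
    st[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc,
                    h_prev = h, c_prev = cc, m = m)
    h <- m * (o * tc) + (1 - m) * h
    cc <- m * ctil + (1 - m) * cc
    out[rows, ] <- h
  }
  if (!ad_is(XW) && !ad_is(Wh)) return(out)
  tape <- if (ad_is(XW)) XW$tape else Wh$tape
  .ad_push(tape, out, c(.pid(XW), .pid(Wh)), function(gr) {
    gXW <- matrix(0, nrow(XWv), 4L * H)
    gWh <- matrix(0, H, 4L * H)
    dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
    for (t in rev(steps)) {
      s <- st[[t]]
      rows <- (t - 1L) * B + seq_len(B)
      dh <- gr[rows, , drop = FALSE] + dh_carry
      dht <- dh * s$m
      dc <- dc_carry
      dctil <- dc * s$m + dht * s$o * (1 - s$tc^2)
      dG <- cbind((dctil * s$g) * s$i * (1 - s$i),
                  (dctil * s$c_prev) * s$f * (1 - s$f),
                  (dht * s$tc) * s$o * (1 - s$o),
                  (dctil * s$i) * (1 - s$g^2))
      gXW[rows, ] <- dG
      gWh <- gWh + crossprod(s$h_prev, dG)
      dh_carry <- dh * (1 - s$m) + dG %*% t(Whv)
      dc_carry <- dc * (1 - s$m) + dctil * s$f
    }
    list(if (ad_is(XW)) gXW else NULL, if (ad_is(Wh)) gWh else NULL)
  })
}

# Fused multi-head self-attention over a flat time-major batch.
# Q, K, V: n x W (n = Tlen * B); mask: B x Tlen 0/1 (masked keys excluded).
# Output n x W, heads concatenated along columns. One tape node.
op_mha <- function(Q, K, V, mask, B, Tlen, n_heads, scale) {
  Qv <- ad_value(Q); Kv <- ad_value(K); Vv <- ad_value(V)
  W <- ncol(Qv); dk <- W %/% n_heads
  out <- matrix(0, nrow(Qv), W)
  Astore <- vector("list", B * n_heads)
  rows_of <- function(g) seq(g, by = B, length.out = Tlen)
  for (g in seq_len(B)) {
    rows <- rows_of(g)
    pen <- ifelse(mask[g, ] > 0, 0, -1e9)
    for (h in seq_len(n_heads)) {
      cl <- (h - 1L) * dk + seq_len(dk)
      S <- tcrossprod(Qv[rows, cl, drop = FALSE], Kv[rows, cl, drop = FALSE]) * scale
      S <- sweep(S, 2L, pen, "+")
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      Astore[[(g - 1L) * n_heads + h]] <- A
      out[rows, cl] <- A %*% Vv[rows, cl, drop = FALSE]
    }
  }
  if (!ad_is(Q) && !ad_is(K) && !ad_is(V)) return(out)
  tape <- if (ad_is(Q)) Q$tape else if (ad_is(K)) K$tape else V$tape
  .ad_push(tape, out, c(.pid(Q), .pid(K), .pid(V)), function(gr) {
    gQ <- matrix(0, nrow(Qv), W); gK <- gQ; gV <- gQ
    for (g in seq_len(B)) {
      rows <- rows_of(g)
      for (h in seq_len(n_heads)) {
        cl <- (h - 1L) * dk + seq_len(dk)
        A <- Astore[[(g - 1L) * n_heads + h]]
        go <- gr[rows, cl, drop = FALSE]
        gA <- tcrossprod(go, Vv[rows, cl, drop = FALSE])
        gS <- A * (gA - rowSums(gA * A))
        gQ[rows, cl] <- (gS %*% Kv[rows, cl, drop = FALSE]) * scale
        gK[rows, cl] <- crossprod(gS, Qv[rows, cl, drop = FALSE]) * scale
        gV[rows, cl] <- crossprod(A, go)
      }
    }
    list(if (ad_is(Q)) gQ else NULL, if (ad_is(K)) gK else NULL,
         if (ad_is(V)) gV else NULL)
  })
}

# segment softmax of a score column within groups, padded rows masked to 0
# scores: n x 1; group: n ints in 1..ngroups; mask: n x 1 in {0,1}
seg_softmax <- function(scores, group, ngroups, mask = NULL) {
  sv <- as.numeric(ad_value(scores))
  if (is.null(mask)) mask <- matrix(1, length(sv), 1L)
  mv <- as.numeric(mask)
  # constant per-group max over unmasked rows (softmax shift, not tracked)
  mx <- tapply(ifelse(mv > 0, sv, -Inf), group, max)
  shift <- rep(0, ngroups)
  shift[as.integer(names(mx))] <- ifelse(is.finite(mx), mx, 0)
  e <- op_mul(op_exp(op_sub(scores, matrix(shift[group], ncol = 1L))), mask)
  tot <- op_rowsum(e, group, ngroups)
  op_div(e, op_gather(tot, group))
}

# L2-normalize rows (safe for zero rows via eps)
l2_normalize_rows <- function(z, eps = 1e-12) {
  d <- ncol(ad_value(z))
  ssq <- op_mm(op_mul(z, z), matrix(1, d, 1L))
  op_div(z, op_sqrt(op_add(ssq, matrix(eps, 1L, 1L))))
}
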