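# Reverse-mode automatic differentiation on numeric arrays.
#
# A tape is an environment holding nodes in creation order; each node is an
# environment with the forward value, an accumulated gradient slot, its parent
# nodes and a backward closure mapping the output gradient to parent
# gradients. Creation order is a topological order of the forward graph, so
# backpropagation is a single reverse sweep. Everything downstream (attention
# encoders, LSTM, VAE, distillation losses, integrated gradients) is built on
# these primitives.

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

.tp_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# val: numeric vector/matrix/array. requires_grad leaves collect gradients.
tp_leaf <- function(tape, val, requires_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- NULL
  nd$bwd <- NULL
  nd$req <- requires_grad
  .tp_push(tape, nd)
}

# parents: list of nodes; bwd: function(g, node) -> list of parent gradients
# (NULL entries allowed for parents that need no gradient).
tp_op <- function(tape, val, parents, bwd) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  nd$req <- TRUE
  .tp_push(tape, nd)
}

.acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backward sweep from `root` (a scalar-valued node unless `seed` is given).
tp_backward <- function(tape, root, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim = if (is.null(dim(root$val))) length(root$val) else dim(root$val))
  root$grad <- seed
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bwd)) next
    pg <- nd$bwd(nd$grad, nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(pg[[j]]) && isTRUE(ps[[j]]$req)) .acc(ps[[j]], pg[[j]])
    }
    if (!isTRUE(nd$keep_grad)) nd$grad <- NULL
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

tp_matmul <- function(tape, a, b) {
  v <- a$val %*% b$val
  tp_op(tape, v, list(a, b), function(g, nd) {
    list(g %*% t(nd$parents[[2]]$val), crossprod(nd$parents[[1]]$val, g))
  })
}

tp_add <- function(tape, a, b) {
  tp_op(tape, a$val + b$val, list(a, b), function(g, nd) list(g, g))
}

tp_sub <- function(tape, a, b) {
  tp_op(tape, a$val - b$val, list(a, b), function(g, nd) list(g, -g))
}

tp_mul <- function(tape, a, b) {
  tp_op(tape, a$val * b$val, list(a, b), function(g, nd) {
    list(g * nd$parents[[2]]$val, g * nd$parents[[1]]$val)
  })
}

tp_scale <- function(tape, a, s) {
  tp_op(tape, a$val * s, list(a), function(g, nd) list(g * s))
}

tp_shift <- function(tape, a, s) {
  tp_op(tape, a$val + s, list(a), function(g, nd) list(g))
}

# matrix + bias row vector, broadcast over rows
tp_bias <- function(tape, a, b) {
  v <- sweep(a$val, 2L, b$val, "+")
  tp_op(tape, v, list(a, b), function(g, nd) list(g, colSums(g)))
}

tp_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$val))
  nd <- tp_op(tape, v, list(a), function(g, nd) list(g * nd$val * (1 - nd$val)))
  nd
}

tp_tanh <- function(tape, a) {
  v <- tanh(a$val)
  tp_op(tape, v, list(a), function(g, nd) list(g * (1 - nd$val^2)))
}

tp_relu <- function(tape, a) {
  v <- pmax(a$val, 0)
  tp_op(tape, v, list(a), function(g, nd) list(g * (nd$parents[[1]]$val > 0)))
}

tp_exp <- function(tape, a) {
  v <- exp(a$val)
  tp_op(tape, v, list(a), function(g, nd) list(g * nd$val))
}

tp_square <- function(tape, a) {
  tp_op(tape, a$val^2, list(a), function(g, nd) list(2 * g * nd$parents[[1]]$val))
}

tp_sum <- function(tape, a) {
  tp_op(tape, sum(a$val), list(a), function(g, nd) {
    d <- dim(nd$parents[[1]]$val)
    list(array(as.numeric(g), dim = if (is.null(d)) length(nd$parents[[1]]$val) else d))
  })
}

tp_mean <- function(tape, a) {
  n <- length(a$val)
  tp_op(tape, mean(a$val), list(a), function(g, nd) {
    d <- dim(nd$parents[[1]]$val)
    list(array(as.numeric(g) / n, dim = if (is.null(d)) n else d))
  })
}

# weighted sum: sum(a * w) for constant weights w (e.g. masks)
tp_dotc <- function(tape, a, w) {
  tp_op(tape, sum(a$val * w), list(a), function(g, nd) list(as.numeric(g) * w))
}

# elementwise product with a constant array (masking)
tp_mulc <- function(tape, a, w) {
  tp_op(tape, a$val * w, list(a), function(g, nd) list(g * w))
}

tp_slice_cols <- function(tape, a, idx) {
  v <- a$val[, idx, drop = FALSE]
  tp_op(tape, v, list(a), function(g, nd) {
    out <- array(0, dim = dim(nd$parents[[1]]$val))
    out[, idx] <- g
    list(out)
  })
}

tp_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(x) x$val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tp_op(tape, do.call(cbind, vals), nodes, function(g, nd) {
    lapply(seq_along(nd$parents), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# row gather with scatter-add backward; idx may repeat rows
tp_gather_rows <- function(tape, a, idx) {
  v <- a$val[idx, , drop = FALSE]
  tp_op(tape, v, list(a), function(g, nd) {
    p <- nd$parents[[1]]$val
    out <- rowsum(g, group = idx, reorder = FALSE)
    full <- matrix(0, nrow(p), ncol(p))
    full[as.integer(rownames(out)), ] <- out
    list(full)
  })
}

# gather along the first (batch) dimension of a 3D array B x T x d
tp_gather_b3 <- function(tape, a, idx) {
  v <- a$val[idx, , , drop = FALSE]
  tp_op(tape, v, list(a), function(g, nd) {
    p <- nd$parents[[1]]$val
    dm <- dim(p)
    gm <- g
    dim(gm) <- c(length(idx), dm[2] * dm[3])
    out <- rowsum(gm, group = idx, reorder = FALSE)
    full <- matrix(0, dm[1], dm[2] * dm[3])
    full[as.integer(rownames(out)), ] <- out
    dim(full) <- dm
    list(full)
  })
}

# reshape (column-major; collapsing leading dims keeps element order)
tp_reshape <- function(tape, a, dims) {
  v <- a$val
  old <- dim(v)
  dim(v) <- dims
  tp_op(tape, v, list(a), function(g, nd) {
    dim(g) <- if (is.null(old)) length(g) else old
    list(g)
  })
}

# stack a list of B x d matrices into B x T x d
tp_stack3 <- function(tape, nodes) {
  B <- nrow(nodes[[1]]$val); d <- ncol(nodes[[1]]$val); T <- length(nodes)
  v <- array(0, dim = c(B, T, d))
  for (t in seq_len(T)) v[, t, ] <- nodes[[t]]$val
  tp_op(tape, v, nodes, function(g, nd) {
    lapply(seq_along(nd$parents), function(t) {
      gt <- g[, t, ]
      if (is.null(dim(gt))) gt <- matrix(gt, nrow = dim(g)[1])
      gt
    })
  })
}

# concatenate 3D arrays B x T_i x d along the token dimension
tp_cat3 <- function(tape, nodes) {
  Ts <- vapply(nodes, function(x) dim(x$val)[2], 1L)
  ends <- cumsum(Ts); starts <- ends - Ts + 1L
  B <- dim(nodes[[1]]$val)[1]; d <- dim(nodes[[1]]$val)[3]
  v <- array(0, dim = c(B, sum(Ts), d))
  for (j in seq_along(nodes)) v[, starts[j]:ends[j], ] <- nodes[[j]]$val
  tp_op(tape, v, nodes, function(g, nd) {
    lapply(seq_along(nd$parents), function(j) g[, starts[j]:ends[j], , drop = FALSE])
  })
}

# add a learned positional table P (T x d) to a B x T x d array
tp_add_pos <- function(tape, a, p) {
  B <- dim(a$val)[1]
  # column-major: rep(each = B) lays p[t, k] onto slot (b, t, k) for every b
  v <- a$val + rep(p$val, each = B)
  tp_op(tape, v, list(a, p), function(g, nd) {
    dm <- dim(g)
    gp <- g
    dim(gp) <- c(dm[1], dm[2] * dm[3])
    gp <- colSums(gp)
    dim(gp) <- c(dm[2], dm[3])
    list(g, gp)
  })
}

# row-wise softmax of a matrix
tp_rowsoftmax <- function(tape, a) {
  v <- .rowsoftmax(a$val)
  tp_op(tape, v, list(a), function(g, nd) {
    s <- nd$val
    gs <- g * s
    list(gs - s * rowSums(gs))
  })
}

.rowsoftmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# slice K[, j, ] keeping matrix shape without an extra copy when possible
.slice2 <- function(X, j, B, d) {
  out <- X[, j, ]
  if (is.null(dim(out))) dim(out) <- c(B, d)
  out
}

# ---- scaled dot-product attention over batched token arrays ----------------
#
# Q: B x Tq x d, K, V: B x Tk x d (one head). Scores are scaled by 1/sqrt(d).
# Implemented as a single tape op with hand-derived backward, vectorised over
# the batch (loops run over token indices only).
tp_attention3 <- function(tape, Q, K, V) {
  fw <- .attn3_fwd(Q$val, K$val, V$val)
  nd <- tp_op(tape, fw$O, list(Q, K, V), function(g, nd) {
    .attn3_bwd(g, nd$parents[[1]]$val, nd$parents[[2]]$val, nd$parents[[3]]$val, nd$A)
  })
  nd$A <- fw$A
  nd
}

# Both passes loop over keys only: queries are handled as a flattened
# (B*Tq) x d matrix, with each key row replicated over the query dimension.
.attn3_fwd <- function(Q, K, V) {
  dm <- dim(Q); B <- dm[1]; Tq <- dm[2]; d <- dm[3]; Tk <- dim(K)[2]
  sc <- 1 / sqrt(d)
  Qm <- Q; dim(Qm) <- c(B * Tq, d)
  idx <- rep(seq_len(B), times = Tq)
  S <- matrix(0, B * Tq, Tk)
  for (j in seq_len(Tk)) {
    Kj <- .slice2(K, j, B, d)
    S[, j] <- rowSums(Qm * Kj[idx, , drop = FALSE])
  }
  A <- .rowsoftmax(S * sc)
  O <- matrix(0, B * Tq, d)
  for (j in seq_len(Tk)) {
    Vj <- .slice2(V, j, B, d)
    O <- O + A[, j] * Vj[idx, , drop = FALSE]
  }
  dim(O) <- c(B, Tq, d)
  A3 <- A; dim(A3) <- c(B, Tq, Tk)
  list(O = O, A = A3)
}

.attn3_bwd <- function(gO, Q, K, V, A) {
  dm <- dim(Q); B <- dm[1]; Tq <- dm[2]; d <- dm[3]; Tk <- dim(K)[2]
  sc <- 1 / sqrt(d)
  idx <- rep(seq_len(B), times = Tq)
  Qm <- Q; dim(Qm) <- c(B * Tq, d)
  gOm <- gO; dim(gOm) <- c(B * Tq, d)
  Am <- A; dim(Am) <- c(B * Tq, Tk)
  gA <- matrix(0, B * Tq, Tk)
  gV <- array(0, dim = dim(V))
  for (j in seq_len(Tk)) {
    Vj <- .slice2(V, j, B, d)
    gA[, j] <- rowSums(gOm * Vj[idx, , drop = FALSE])
    gV[, j, ] <- rowsum(Am[, j] * gOm, group = idx)
  }
  # softmax backward per query row: gS = A * (gA - rowSums(gA * A))
  gS <- Am * (gA - rowSums(gA * Am)) * sc
  gQm <- matrix(0, B * Tq, d)
  gK <- array(0, dim = dim(K))
  for (j in seq_len(Tk)) {
    Kj <- .slice2(K, j, B, d)
    gQm <- gQm + gS[, j] * Kj[idx, , drop = FALSE]
    gK[, j, ] <- rowsum(gS[, j] * Qm, group = idx)
  }
  dim(gQm) <- c(B, Tq, d)
  list(gQm, gK, gV)
}

# mean over the token dimension of B x T x d -> B x d
tp_meantok <- function(tape, a) {
  dm <- dim(a$val)
  v <- apply(a$val, c(1, 3), mean)
  if (is.null(dim(v))) v <- matrix(v, dm[1], dm[3])
  tp_op(tape, v, list(a), function(g, nd) {
    dmp <- dim(nd$parents[[1]]$val)
    out <- array(0, dim = dmp)
    for (t in seq_len(dmp[2])) out[, t, ] <- g / dmp[2]
    list(out)
  })
}
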