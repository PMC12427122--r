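# Parameter containers, initialisation and the Adam optimiser.
#
# Model parameters live in nested named lists of plain numeric arrays. At each
# training step the list is mirrored onto a fresh tape as gradient-collecting
# leaves; after the backward sweep the gradients are read back in the same
# structure and fed to Adam.

nn_glorot <- function(n_in, n_out, gain = 1) {
  lim <- gain * sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_zeros <- function(...) array(0, dim = c(...))

# mirror a nested list of arrays as tape leaves
tp_params <- function(tape, params) {
  if (is.list(params)) return(lapply(params, function(p) tp_params(tape, p)))
  tp_leaf(tape, params, requires_grad = TRUE)
}

# read gradients back in the same nested structure (zeros where untouched)
tp_grads <- function(pnodes) {
  if (is.list(pnodes)) return(lapply(pnodes, tp_grads))
  g <- pnodes$grad
  if (is.null(g)) g <- array(0, dim = if (is.null(dim(pnodes$val))) length(pnodes$val) else dim(pnodes$val))
  g
}

.flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], paste0(prefix, ".", i))
    } else {
      out[[prefix]] <<- x
    }
  }
  walk(p, "p")
  out
}

.unflatten_into <- function(template, flat) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    i <<- i + 1L
    flat[[i]]
  }
  fill(template)
}

adam_new <- function(params, lr = 3e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0) {
  fl <- .flatten_params(params)
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps; st$t <- 0L
  st$wd <- weight_decay
  st$m <- lapply(fl, function(x) x * 0)
  st$v <- lapply(fl, function(x) x * 0)
  st
}

adam_step <- function(opt, params, grads) {
  fp <- .flatten_params(params)
  fg <- .flatten_params(grads)
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(fp)) {
    g <- fg[[i]]
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g^2
    mh <- opt$m[[i]] / bc1
    vh <- opt$v[[i]] / bc2
    # decoupled weight decay (AdamW)
    fp[[i]] <- fp[[i]] - opt$lr * (mh / (sqrt(vh) + opt$eps) + opt$wd * fp[[i]])
  }
  .unflatten_into(params, fp)
}

# ---- layer builders (tape graph constructors) ------------------------------

nn_linear_init <- function(n_in, n_out) {
  list(W = nn_glorot(n_in, n_out), b = nn_zeros(n_out))
}

tp_linear <- function(tape, x, p) {
  tp_bias(tape, tp_matmul(tape, x, p$W), p$b)
}

# one transformer block: multi-head self-attention + position-wise FFN, both
# with residual connections. h is B x T x d; p holds Wq/Wk/Wv/Wo (d x d with
# bias) and ff1/ff2.
nn_block_init <- function(d, d_ff) {
  list(
    q = nn_linear_init(d, d), k = nn_linear_init(d, d),
    v = nn_linear_init(d, d), o = nn_linear_init(d, d),
    f1 = nn_linear_init(d, d_ff), f2 = nn_linear_init(d_ff, d)
  )
}

tp_block <- function(tape, h, p, n_heads, collect = NULL, dropout = 0) {
  dm <- dim(h$val); B <- dm[1]; T <- dm[2]; d <- dm[3]
  dh <- d %/% n_heads
  hm <- tp_reshape(tape, h, c(B * T, d))
  Qm <- tp_linear(tape, hm, p$q)
  Km <- tp_linear(tape, hm, p$k)
  Vm <- tp_linear(tape, hm, p$v)
  heads <- vector("list", n_heads)
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1) * dh + 1):(hd * dh)
    Q3 <- tp_reshape(tape, tp_slice_cols(tape, Qm, cols), c(B, T, dh))
    K3 <- tp_reshape(tape, tp_slice_cols(tape, Km, cols), c(B, T, dh))
    V3 <- tp_reshape(tape, tp_slice_cols(tape, Vm, cols), c(B, T, dh))
    at <- tp_attention3(tape, Q3, K3, V3)
    if (!is.null(collect)) collect(at$A)
    heads[[hd]] <- tp_reshape(tape, at, c(B * T, dh))
  }
  om <- tp_linear(tape, tp_cbind(tape, heads), p$o)
  h1 <- tp_add(tape, h, tp_reshape(tape, om, c(B, T, d)))
  # feed-forward with residual
  h1m <- tp_reshape(tape, h1, c(B * T, d))
  hid <- tp_relu(tape, tp_linear(tape, h1m, p$f1))
  if (dropout > 0) {
    mask <- matrix(stats::rbinom(length(hid$val), 1, 1 - dropout) / (1 - dropout),
                   nrow(hid$val), ncol(hid$val))
    hid <- tp_mulc(tape, hid, mask)
  }
  ff <- tp_linear(tape, hid, p$f2)
  tp_add(tape, h1, tp_reshape(tape, ff, c(B, T, d)))
}

# ---- LSTM ------------------------------------------------------------------

nn_lstm_init <- function(d_in, d_hidden) {
  list(
    W = nn_glorot(d_in, 4 * d_hidden),
    U = nn_glorot(d_hidden, 4 * d_hidden),
    b = nn_zeros(4 * d_hidden)
  )
}

# xs: list over time of B x d_in tape nodes; returns list over time of B x h
tp_lstm_run <- function(tape, xs, p, d_hidden) {
  B <- nrow(xs[[1]]$val)
  h <- tp_leaf(tape, matrix(0, B, d_hidden))
  cc <- tp_leaf(tape, matrix(0, B, d_hidden))
  ii <- 1:d_hidden; ff <- (d_hidden + 1):(2 * d_hidden)
  oo <- (2 * d_hidden + 1):(3 * d_hidden); gg <- (3 * d_hidden + 1):(4 * d_hidden)
  out <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- tp_bias(tape, tp_add(tape, tp_matmul(tape, xs[[t]], p$W),
                              tp_matmul(tape, h, p$U)), p$b)
    gi <- tp_sigmoid(tape, tp_slice_cols(tape, z, ii))
    gf <- tp_sigmoid(tape, tp_slice_cols(tape, z, ff))
    go <- tp_sigmoid(tape, tp_slice_cols(tape, z, oo))
    gc <- tp_tanh(tape, tp_slice_cols(tape, z, gg))
    cc <- tp_add(tape, tp_mul(tape, gf, cc), tp_mul(tape, gi, gc))
    h <- tp_mul(tape, go, tp_tanh(tape, cc))
    out[[t]] <- h
  }
  out
}
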