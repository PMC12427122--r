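# Modality and drug encoders, and the cross-modal fusion primitive.
#
# Each omics feature vector is partitioned into contiguous groups, each group
# linearly embedded to d_model with a learned positional embedding, and the
# resulting token sequence passed through stacked multi-head self-attention +
# feed-forward blocks. Drugs are embedded token sequences run through a
# bi-directional LSTM and pooled over non-PAD positions.

#' Encoder hyperparameters
#'
#' @param d_model embedding width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_layers stacked self-attention blocks per omics encoder.
#' @param n_tokens contiguous feature groups (tokens) per omics modality;
#'   capped at the modality's feature count.
#' @param dropout dropout probability on the feed-forward hidden layer during
#'   training (0 disables; prediction is always deterministic).
#' @param max_smiles_len maximum SMILES token sequence length.
#' @param pool drug pooling: `"mean"` over non-PAD positions or `"last"`
#'   hidden state.
#' @param d_ff feed-forward hidden width (default `2 * d_model`).
#' @param head_hidden regression head hidden width.
#' @return list of class `mkdr_encoder_config`.
#' @export
encoder_config <- function(d_model = 32, n_heads = 4, n_layers = 2,
                           n_tokens = 16, dropout = 0, max_smiles_len = 60,
                           pool = c("mean", "last"), d_ff = 2 * d_model,
                           head_hidden = 32) {
  pool <- match.arg(pool)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (n_tokens < 1) stop("n_tokens must be >= 1")
  structure(list(d_model = d_model, n_heads = n_heads, n_layers = n_layers,
                 n_tokens = n_tokens, dropout = dropout,
                 max_smiles_len = max_smiles_len, pool = pool, d_ff = d_ff,
                 head_hidden = head_hidden),
            class = "mkdr_encoder_config")
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V`: every output row is a convex combination of
#' the rows of `V`, with weights that sum to 1 per query.
#'
#' @param Q queries (nq x d), `K` keys (nk x d), `V` values (nk x dv).
#' @param d scaling width (default `ncol(Q)`); must be positive.
#' @return list with `out` (nq x dv) and `weights` (nq x nk).
#' @examples
#' a <- attention(matrix(1), matrix(c(1, -1), 2, 1), matrix(c(1, 0), 2, 1))
#' a$out  # plogis(2) = 0.8808
#' @export
attention <- function(Q, K, V, d = ncol(Q)) {
  if (d <= 0) stop("d must be positive")
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("K and V row counts differ")
  W <- .rowsoftmax(Q %*% t(K) / sqrt(d))
  list(out = W %*% V, weights = W)
}

#' Cross-modal fusion with the drug as query
#'
#' Concatenates the three omics token matrices as keys/values and attends
#' with the drug representation as the single query; optionally adds a
#' residual connection from the drug representation (`residual = FALSE`
#' recovers the plain attention output).
#'
#' @param h_drug drug representation, numeric vector of length d.
#' @param h_ge,h_cnv,h_mu omics token matrices (tokens x d).
#' @param residual add `h_drug` to the fused output (default TRUE).
#' @return list with `Z` (length-d fused vector) and `weights` (one weight
#'   per concatenated omics token, summing to 1) split by modality in
#'   `weights_by_modality`.
#' @export
fuse <- function(h_drug, h_ge, h_cnv, h_mu, residual = TRUE) {
  d <- length(h_drug)
  KV <- rbind(h_ge, h_cnv, h_mu)
  if (ncol(KV) != d) stop("embedding widths differ")
  a <- attention(matrix(h_drug, 1), KV, KV, d = d)
  z <- drop(a$out)
  if (residual) z <- z + h_drug
  w <- drop(a$weights)
  sizes <- c(ge = nrow(h_ge), cnv = nrow(h_cnv), mu = nrow(h_mu))
  grp <- rep(names(sizes), times = sizes)
  list(Z = z, weights = w,
       weights_by_modality = vapply(split(w, grp)[unique(grp)], sum, 1))
}

# contiguous feature groups of near-equal size
.feature_groups <- function(p, n_tokens) {
  T <- min(n_tokens, p)
  sizes <- rep(p %/% T, T) + (seq_len(T) <= p %% T)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(T), function(g) starts[g]:ends[g])
}

.modality_params_init <- function(p, cfg) {
  groups <- .feature_groups(p, cfg$n_tokens)
  list(
    emb = lapply(groups, function(g) nn_linear_init(length(g), cfg$d_model)),
    pos = matrix(stats::rnorm(length(groups) * cfg$d_model, sd = 0.02),
                 length(groups), cfg$d_model),
    blocks = lapply(seq_len(cfg$n_layers), function(i) nn_block_init(cfg$d_model, cfg$d_ff))
  )
}

.drug_params_init <- function(vocab_size, cfg) {
  h <- cfg$d_model %/% 2
  list(
    # row 1 is the PAD slot (id 0); token id v lives at row v + 1
    E = matrix(stats::rnorm(vocab_size * cfg$d_model, sd = 0.1), vocab_size, cfg$d_model),
    fwd = nn_lstm_init(cfg$d_model, h),
    bwd = nn_lstm_init(cfg$d_model, h)
  )
}

# omics encoder graph: x node (B x p) -> token node (B x T x d)
.encode_modality_nodes <- function(tape, x, pnodes, groups, cfg, collect = NULL,
                                   train = FALSE) {
  toks <- lapply(seq_along(groups), function(g) {
    tp_linear(tape, tp_slice_cols(tape, x, groups[[g]]), pnodes$emb[[g]])
  })
  h <- tp_add_pos(tape, tp_stack3(tape, toks), pnodes$pos)
  dp <- if (train) cfg$dropout else 0
  for (bl in pnodes$blocks) h <- tp_block(tape, h, bl, cfg$n_heads, collect, dropout = dp)
  h
}

# drug encoder graph: integer token matrix (B x L, PAD = 0) -> B x d node
.encode_drug_nodes <- function(tape, token_mat, pnodes, cfg) {
  B <- nrow(token_mat); L <- ncol(token_mat)
  lens <- rowSums(token_mat != 0L)
  if (any(lens == 0)) stop("all-PAD token sequence for drug row ", which(lens == 0)[1])
  d <- cfg$d_model; h <- d %/% 2
  # reversed-within-length copy for the backward direction
  rev_mat <- token_mat
  for (i in seq_len(B)) rev_mat[i, seq_len(lens[i])] <- rev(token_mat[i, seq_len(lens[i])])
  emb_at <- function(mat, t) tp_gather_rows(tape, pnodes$E, mat[, t] + 1L)
  xs_f <- lapply(seq_len(L), function(t) emb_at(token_mat, t))
  xs_b <- lapply(seq_len(L), function(t) emb_at(rev_mat, t))
  hs_f <- tp_lstm_run(tape, xs_f, pnodes$fwd, h)
  hs_b <- tp_lstm_run(tape, xs_b, pnodes$bwd, h)
  if (cfg$pool == "mean") {
    acc <- NULL
    for (t in seq_len(L)) {
      mask <- matrix((token_mat[, t] != 0L) / lens, B, d)
      term <- tp_mulc(tape, tp_cbind(tape, list(hs_f[[t]], hs_b[[t]])), mask)
      acc <- if (is.null(acc)) term else tp_add(tape, acc, term)
    }
    acc
  } else {
    # last non-PAD hidden state in each direction
    acc <- NULL
    for (t in seq_len(L)) {
      mask <- matrix(as.numeric(lens == t), B, d)
      term <- tp_mulc(tape, tp_cbind(tape, list(hs_f[[t]], hs_b[[t]])), mask)
      acc <- if (is.null(acc)) term else tp_add(tape, acc, term)
    }
    acc
  }
}

#' Encode one omics profile
#'
#' Runs a modality's self-attention encoder on a single feature vector in
#' eval mode (deterministic).
#'
#' @param model a fitted or freshly initialised `mkdr_model`.
#' @param x numeric feature vector of the modality's width.
#' @param modality `"ge"`, `"cnv"` or `"mu"`.
#' @return list with `tokens` (n_tokens x d_model matrix) and `pooled`
#'   (mean over tokens, length d_model).
#' @export
encode_modality <- function(model, x, modality = c("ge", "cnv", "mu")) {
  modality <- match.arg(modality)
  p <- model$dims[[paste0("n_", modality)]]
  if (length(x) != p) stop(sprintf("expected %d features for %s, got %d", p, modality, length(x)))
  tape <- tp_new()
  xn <- tp_leaf(tape, matrix(as.numeric(x), 1))
  pn <- tp_params(tape, model$params[[modality]])
  h <- .encode_modality_nodes(tape, xn, pn, model$groups[[modality]], model$cfg)
  tokens <- matrix(h$val[1, , ], dim(h$val)[2], dim(h$val)[3])
  list(tokens = tokens, pooled = colMeans(tokens))
}

#' Encode a drug token sequence
#'
#' Embeds the integer token sequence and runs the bi-directional LSTM,
#' pooling per the model's configuration. The embedding is invariant to
#' trailing PAD (0) tokens.
#'
#' @param model `mkdr_model`.
#' @param tokens integer token id vector (PAD = 0 allowed as trailing
#'   padding; an all-PAD sequence is an error).
#' @return numeric vector of length d_model.
#' @export
encode_drug <- function(model, tokens) {
  if (any(tokens < 0) || any(tokens >= model$dims$vocab_size)) stop("token id outside vocabulary")
  tape <- tp_new()
  pn <- tp_params(tape, model$params$drug)
  out <- .encode_drug_nodes(tape, matrix(as.integer(tokens), 1), pn, model$cfg)
  drop(out$val)
}
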