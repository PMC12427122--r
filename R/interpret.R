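# Integrated-gradients attribution over input features, modality-level
# contribution shares, and top-k feature ranking.
#
# Attribution of feature i for input x against baseline b uses the left
# Riemann approximation of the path integral:
#   a_i = (x_i - b_i) * (1/steps) * sum_k df/dx_i at b + (k/steps)(x - b),
# k = 0..steps-1. For a linear model this is exact at any step count; in
# general the attributions sum to f(x) - f(b) as steps grows (completeness),
# and the residual is reported as the completeness gap.

#' Path-integral attributions for an arbitrary differentiable function
#'
#' Low-level integrated-gradients engine: the caller supplies a gradient
#' oracle evaluated at a batch of path points.
#'
#' @param grad_fn function taking a (points x features) matrix and returning
#'   `list(grad = matrix of the same shape, value = numeric per row)`.
#' @param x input feature vector.
#' @param baseline baseline vector, same length (`steps >= 8` enforced).
#' @param steps number of Riemann steps.
#' @return list with `attributions`, `f_x`, `f_baseline`,
#'   `completeness_gap`.
#' @export
ig_path_attributions <- function(grad_fn, x, baseline, steps = 128) {
  if (steps < 8) stop("steps must be >= 8")
  if (length(x) != length(baseline)) stop("baseline shape differs from input")
  alphas <- c(seq(0, steps - 1) / steps, 1)
  path <- outer(alphas, x - baseline, "*") + matrix(baseline, steps + 1, length(x), byrow = TRUE)
  gv <- grad_fn(path)
  if (any(!is.finite(gv$grad))) stop("non-differentiable path point (non-finite gradient)")
  g_mean <- colMeans(gv$grad[seq_len(steps), , drop = FALSE])
  a <- (x - baseline) * g_mean
  f_b <- gv$value[1]; f_x <- gv$value[steps + 1]
  list(attributions = a, f_x = f_x, f_baseline = f_b,
       completeness_gap = abs(sum(a) - (f_x - f_b)))
}

# model-view input row + baseline for one cell under the model's role;
# in ge_only mode the completion happens on-tape, so only GE is assembled
.ig_view <- function(model, bundle, cell_id, completer, fill, mode) {
  if (mode == "ge_only") {
    idx <- match(cell_id, bundle$omics$sample_ids)
    if (is.na(idx) || !bundle$omics$observed[idx, "ge"]) {
      stop("gene expression unobserved for cell ", cell_id)
    }
    return(list(ge = unname(bundle$omics$ge[idx, , drop = FALSE])))
  }
  .model_inputs(model, bundle$omics, cell_id, completer = completer, fill = fill)
}

#' Integrated-gradients attribution for one (cell, drug) prediction
#'
#' Attributes the model's prediction to its input features. For a student,
#' `mode = "completed"` (default) attributes against the completed
#' three-modality view — CNV/MU importance is measured at the completed
#' representation — while `mode = "ge_only"` differentiates end-to-end
#' through the VAE completer and attributes only the observed gene
#' expression. Drug-token attributions use a zero-embedding baseline on the
#' same path and are reported separately.
#'
#' @param model fitted `mkdr_model`.
#' @param bundle dataset bundle.
#' @param cell_id,drug_id identifiers of the pair.
#' @param steps Riemann steps (>= 8; default 128).
#' @param baseline `"train_mean"` (per-feature mean of the model's view over
#'   training cells) or `"zero"`.
#' @param completer,fill completion path, as in [predict.mkdr_model()].
#' @param mode `"completed"` or `"ge_only"` (students only).
#' @param include_drug also attribute drug tokens (default TRUE).
#' @return object of class `mkdr_attribution`: per-feature signed scores by
#'   modality, drug token scores, `f_x`, `f_baseline`, `completeness_gap`.
#' @export
integrated_gradients <- function(model, bundle, cell_id, drug_id, steps = 128,
                                 baseline = c("train_mean", "zero"),
                                 completer = NULL, fill = NULL,
                                 mode = c("completed", "ge_only"),
                                 include_drug = TRUE) {
  baseline <- match.arg(baseline)
  mode <- match.arg(mode)
  if (steps < 8) stop("steps must be >= 8")
  if (mode == "ge_only" && is.null(completer)) stop("mode 'ge_only' requires the completer")
  x_in <- .ig_view(model, bundle, cell_id, completer, fill, mode)
  base_in <- .ig_baseline(model, bundle, baseline, completer, fill, mode)
  tokens <- bundle$drugs$token_seqs[[drug_id]]
  if (is.null(tokens)) stop("unknown drug id ", drug_id)
  tokens <- tokens[tokens != 0L]
  n <- steps + 1L
  alphas <- c(seq(0, steps - 1) / steps, 1)
  path_of <- function(x, b) outer(alphas, x - b, "*") + matrix(b, n, length(x), byrow = TRUE)

  tape <- tp_new()
  pn <- tp_params(tape, model$params)
  leaves <- list()
  modalities <- if (mode == "ge_only") "ge" else c("ge", "cnv", "mu")
  for (m in modalities) {
    leaves[[m]] <- tp_leaf(tape, path_of(drop(x_in[[m]]), drop(base_in[[m]])), requires_grad = TRUE)
    leaves[[m]]$keep_grad <- TRUE
  }
  if (mode == "ge_only") {
    pn_vae <- tp_params(tape, completer$params)
    enc <- .vae_encode_nodes(tape, leaves$ge, pn_vae)
    dec <- .vae_decode_nodes(tape, enc$mu, pn_vae)
    leaves$cnv <- dec$cnv
    leaves$mu <- dec$mu_prob
  }
  # drug embeddings along the same path (zero-embedding baseline)
  L <- length(tokens)
  d <- model$cfg$d_model
  E <- model$params$drug$E
  emb_rows <- E[tokens + 1L, , drop = FALSE]
  tok_leaves_f <- vector("list", L)
  tok_leaves_b <- vector("list", L)
  for (t in seq_len(L)) {
    scale_t <- if (include_drug) alphas else rep(1, n)
    lf <- tp_leaf(tape, outer(scale_t, emb_rows[t, ]), requires_grad = include_drug)
    lb <- tp_leaf(tape, outer(scale_t, emb_rows[L - t + 1L, ]), requires_grad = include_drug)
    if (include_drug) { lf$keep_grad <- TRUE; lb$keep_grad <- TRUE }
    tok_leaves_f[[t]] <- lf
    tok_leaves_b[[t]] <- lb
  }
  inputs <- list(cell_idx = seq_len(n), drug_idx = rep(1L, n),
                 token_mat = matrix(tokens, 1))
  fw <- .ig_forward(tape, pn, model, leaves, inputs, tok_leaves_f, tok_leaves_b)
  root <- tp_sum(tape, fw$pred)
  tp_backward(tape, root)

  att <- list()
  for (m in modalities) {
    g <- colMeans(leaves[[m]]$grad[seq_len(steps), , drop = FALSE])
    att[[m]] <- (drop(x_in[[m]]) - drop(base_in[[m]])) * g
    names(att[[m]]) <- bundle$omics$feature_names[[m]]
  }
  if (mode == "ge_only") { att$cnv <- NULL; att$mu <- NULL }
  drug_att <- NULL
  if (include_drug) {
    drug_att <- numeric(L)
    for (t in seq_len(L)) {
      gf <- colMeans(tok_leaves_f[[t]]$grad[seq_len(steps), , drop = FALSE])
      gb <- colMeans(tok_leaves_b[[L - t + 1L]]$grad[seq_len(steps), , drop = FALSE])
      drug_att[t] <- sum(emb_rows[t, ] * (gf + gb))
    }
    names(drug_att) <- names(bundle$drugs$vocab)[match(tokens, bundle$drugs$vocab)]
  }
  preds <- drop(fw$pred$val)
  f_b <- preds[1]; f_x <- preds[n]
  total <- sum(unlist(att)) + sum(drug_att)
  structure(list(ge = att$ge, cnv = att$cnv, mu = att$mu, drug = drug_att,
                 cell_id = cell_id, drug_id = drug_id, steps = steps,
                 mode = mode, f_x = f_x, f_baseline = f_b,
                 completeness_gap = abs(total - (f_x - f_b))),
            class = "mkdr_attribution")
}

# forward with externally supplied modality leaves and drug embedding leaves
.ig_forward <- function(tape, pnodes, model, leaves, inputs, xs_f, xs_b) {
  cfg <- model$cfg
  Hs <- lapply(c("ge", "cnv", "mu"), function(m) {
    .encode_modality_nodes(tape, leaves[[m]], pnodes[[m]], model$groups[[m]], cfg)
  })
  Hcat <- tp_cat3(tape, Hs)
  Kp <- tp_gather_b3(tape, Hcat, inputs$cell_idx)
  h <- cfg$d_model %/% 2
  hs_f <- tp_lstm_run(tape, xs_f, pnodes$drug$fwd, h)
  hs_b <- tp_lstm_run(tape, xs_b, pnodes$drug$bwd, h)
  L <- length(xs_f)
  if (cfg$pool == "mean") {
    acc <- NULL
    for (t in seq_len(L)) {
      term <- tp_scale(tape, tp_cbind(tape, list(hs_f[[t]], hs_b[[t]])), 1 / L)
      acc <- if (is.null(acc)) term else tp_add(tape, acc, term)
    }
    hd <- acc
  } else {
    hd <- tp_cbind(tape, list(hs_f[[L]], hs_b[[L]]))
  }
  Q <- hd # one drug path row per batch row
  B <- length(inputs$cell_idx); d <- cfg$d_model
  at <- tp_attention3(tape, tp_reshape(tape, Q, c(B, 1L, d)), Kp, Kp)
  Z <- tp_reshape(tape, at, c(B, d))
  if (model$residual) Z <- tp_add(tape, Z, Q)
  h1 <- tp_relu(tape, tp_linear(tape, Z, pnodes$head$h1))
  pred <- tp_sigmoid(tape, tp_linear(tape, h1, pnodes$head$h2))
  list(pred = pred)
}

# per-feature mean of the model's input view over training cells
.ig_baseline <- function(model, bundle, baseline, completer, fill, mode) {
  if (baseline == "zero") {
    return(list(ge = rep(0, model$dims$n_ge), cnv = rep(0, model$dims$n_cnv),
                mu = rep(0, model$dims$n_mu)))
  }
  tr_cells <- unique(bundle$responses$cell_id[bundle$responses$split == "train"])
  tr_cells <- intersect(tr_cells, bundle$omics$sample_ids)
  if (mode == "ge_only") {
    ok <- bundle$omics$observed[match(tr_cells, bundle$omics$sample_ids), "ge"]
    ge <- bundle$omics$ge[match(tr_cells[ok], bundle$omics$sample_ids), , drop = FALSE]
    return(list(ge = colMeans(ge)))
  }
  if (model$role == "teacher") {
    ok <- rowSums(bundle$omics$observed[match(tr_cells, bundle$omics$sample_ids), , drop = FALSE]) == 3L
    tr_cells <- tr_cells[ok]
  } else {
    ok <- bundle$omics$observed[match(tr_cells, bundle$omics$sample_ids), "ge"]
    tr_cells <- tr_cells[ok]
  }
  vw <- .model_inputs(model, bundle$omics, tr_cells,
                      completer = if (mode == "ge_only") NULL else completer,
                      fill = if (mode == "ge_only") NULL else fill)
  list(ge = colMeans(vw$ge), cnv = colMeans(vw$cnv), mu = colMeans(vw$mu))
}

#' @export
print.mkdr_attribution <- function(x, ...) {
  cat(sprintf("Integrated gradients: %s x %s (%d steps, mode %s)\n",
              x$cell_id, x$drug_id, x$steps, x$mode))
  cat(sprintf("  f(x) = %.4f, f(baseline) = %.4f, completeness gap %.2e\n",
              x$f_x, x$f_baseline, x$completeness_gap))
  sh <- modality_shares(x)
  if (!attr(sh, "undefined")) {
    cat("  modality shares (%):", paste(sprintf("%s=%.1f", names(sh), sh), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attribute a set of (cell, drug) pairs
#'
#' Runs [integrated_gradients()] over evaluation pairs and aggregates
#' per-feature mean absolute attributions.
#'
#' @param model fitted `mkdr_model`.
#' @param bundle dataset bundle.
#' @param pairs data.frame with `cell_id`, `drug_id`; default: the test
#'   split (capped at `max_pairs`).
#' @param steps,baseline,completer,fill,mode as in [integrated_gradients()].
#' @param max_pairs cap on evaluated pairs.
#' @return object of class `mkdr_attribution_set`: list of per-pair
#'   attributions plus `mean_abs` per modality.
#' @export
attribute_set <- function(model, bundle, pairs = NULL, steps = 64,
                          baseline = "train_mean", completer = NULL,
                          fill = NULL, mode = "completed", max_pairs = 20) {
  if (is.null(pairs)) {
    rows <- which(bundle$responses$split == "test")
    pairs <- bundle$responses[rows, c("cell_id", "drug_id")]
  }
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  atts <- lapply(seq_len(nrow(pairs)), function(i) {
    integrated_gradients(model, bundle, pairs$cell_id[i], pairs$drug_id[i],
                         steps = steps, baseline = baseline,
                         completer = completer, fill = fill, mode = mode)
  })
  modalities <- names(atts[[1]])[names(atts[[1]]) %in% c("ge", "cnv", "mu")]
  modalities <- modalities[!vapply(atts[[1]][modalities], is.null, TRUE)]
  mean_abs <- lapply(modalities, function(m) {
    rowMeans(vapply(atts, function(a) abs(a[[m]]), numeric(length(atts[[1]][[m]]))))
  })
  names(mean_abs) <- modalities
  structure(list(attributions = atts, mean_abs = mean_abs, pairs = pairs),
            class = "mkdr_attribution_set")
}

#' Modality-level contribution shares
#'
#' Percentage of total absolute attribution carried by each omics modality
#' (drug-token attributions are excluded from the denominator). For a set,
#' per-pair shares are averaged.
#'
#' @param x an `mkdr_attribution` or `mkdr_attribution_set`.
#' @return named numeric percentages summing to 100, with attribute
#'   `undefined = TRUE` when all attributions are zero.
#' @export
modality_shares <- function(x) {
  one <- function(a) {
    ms <- c(ge = sum(abs(a$ge)),
            cnv = if (is.null(a$cnv)) NA_real_ else sum(abs(a$cnv)),
            mu = if (is.null(a$mu)) NA_real_ else sum(abs(a$mu)))
    ms <- ms[!is.na(ms)]
    tot <- sum(ms)
    if (tot == 0) return(structure(ms * NA_real_, undefined = TRUE))
    structure(100 * ms / tot, undefined = FALSE)
  }
  if (inherits(x, "mkdr_attribution_set")) {
    per <- lapply(x$attributions, one)
    ok <- !vapply(per, function(p) isTRUE(attr(p, "undefined")), TRUE)
    if (!any(ok)) {
      out <- per[[1]]
      attr(out, "undefined") <- TRUE
      return(out)
    }
    m <- colMeans(do.call(rbind, per[ok]))
    return(structure(m, undefined = FALSE))
  }
  one(x)
}

#' Top-k features by mean absolute attribution
#'
#' Ranks features across all omics modalities by mean absolute integrated-
#' gradients score over the evaluation set; ties are broken by feature name
#' for determinism.
#'
#' @param x `mkdr_attribution_set` (or single `mkdr_attribution`).
#' @param k number of features (default 20); truncated with a warning if it
#'   exceeds the feature count.
#' @return data.frame with rank, feature, modality, score.
#' @export
top_features <- function(x, k = 20) {
  if (k < 1) stop("k must be >= 1")
  if (inherits(x, "mkdr_attribution")) {
    mean_abs <- lapply(x[c("ge", "cnv", "mu")], function(v) if (is.null(v)) NULL else abs(v))
    mean_abs <- mean_abs[!vapply(mean_abs, is.null, TRUE)]
  } else {
    mean_abs <- x$mean_abs
  }
  df <- do.call(rbind, lapply(names(mean_abs), function(m) {
    data.frame(feature = names(mean_abs[[m]]), modality = toupper(m),
               score = unname(mean_abs[[m]]), stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$score, df$feature), ]
  if (k > nrow(df)) {
    warning(sprintf("k = %d exceeds %d features; truncated", k, nrow(df)))
    k <- nrow(df)
  }
  out <- df[seq_len(k), ]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out[, c("rank", "feature", "modality", "score")]
}
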