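# The assembled network: three omics encoders, the drug encoder, drug-as-
# query cross-modal attention fusion, and a sigmoid-bounded regression head.
# Teacher and student share this architecture; only their inputs differ.

#' Initialise an MKDR model
#'
#' Builds the parameter set for the full network. `role = "teacher"` expects
#' all three omics modalities observed (or completed) at prediction time;
#' `role = "student"` expects gene expression plus completed (or mean-filled)
#' CNV/MU, which flow through the same encoders.
#'
#' @param n_ge,n_cnv,n_mu omics feature counts.
#' @param vocab_size drug token vocabulary size (including PAD/UNK).
#' @param cfg [encoder_config()].
#' @param role `"teacher"` or `"student"`.
#' @param residual keep the residual connection from the drug representation
#'   into the fused vector (`FALSE` gives the plain attention fusion).
#' @param seed seed for parameter initialisation.
#' @return object of class `mkdr_model` (untrained until passed through
#'   [train_teacher()]/[train_student()]).
#' @export
mkdr_model <- function(n_ge, n_cnv, n_mu, vocab_size, cfg = encoder_config(),
                       role = c("teacher", "student"), residual = TRUE,
                       seed = 1) {
  role <- match.arg(role)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old), add = TRUE)
  dims <- list(n_ge = n_ge, n_cnv = n_cnv, n_mu = n_mu, vocab_size = vocab_size)
  groups <- list(ge = .feature_groups(n_ge, cfg$n_tokens),
                 cnv = .feature_groups(n_cnv, cfg$n_tokens),
                 mu = .feature_groups(n_mu, cfg$n_tokens))
  params <- list(
    ge = .modality_params_init(n_ge, cfg),
    cnv = .modality_params_init(n_cnv, cfg),
    mu = .modality_params_init(n_mu, cfg),
    drug = .drug_params_init(vocab_size, cfg),
    head = list(h1 = nn_linear_init(cfg$d_model, cfg$head_hidden),
                h2 = nn_linear_init(cfg$head_hidden, 1))
  )
  structure(list(params = params, cfg = cfg, dims = dims, groups = groups,
                 role = role, residual = residual, trained = FALSE,
                 history = NULL, seed = seed),
            class = c(paste0("mkdr_", role), "mkdr_model"))
}

# full forward graph over (cell, drug) pairs.
#   inputs: list(ge, cnv, mu) matrices over the unique cells (rows aligned),
#           token_mat over unique drugs, cell_idx/drug_idx per pair.
#   leaves: optionally pre-made tape leaves for ge/cnv/mu (integrated
#           gradients attaches gradient-collecting leaves here).
.mkdr_forward <- function(tape, pnodes, model, inputs, collect_attn = FALSE,
                          train = FALSE, leaves = NULL) {
  cfg <- model$cfg
  mk_leaf <- function(nm) {
    if (!is.null(leaves[[nm]])) leaves[[nm]] else tp_leaf(tape, inputs[[nm]])
  }
  attn_store <- new.env(parent = emptyenv()); attn_store$fusion <- NULL
  Hs <- lapply(c("ge", "cnv", "mu"), function(m) {
    .encode_modality_nodes(tape, mk_leaf(m), pnodes[[m]], model$groups[[m]],
                           cfg, train = train)
  })
  Hcat <- tp_cat3(tape, Hs)
  Kp <- tp_gather_b3(tape, Hcat, inputs$cell_idx)
  hd <- .encode_drug_nodes(tape, inputs$token_mat, pnodes$drug, cfg)
  Q <- tp_gather_rows(tape, hd, inputs$drug_idx)
  B <- length(inputs$cell_idx); d <- cfg$d_model
  at <- tp_attention3(tape, tp_reshape(tape, Q, c(B, 1L, d)), Kp, Kp)
  Z <- tp_reshape(tape, at, c(B, d))
  if (model$residual) Z <- tp_add(tape, Z, Q)
  h1 <- tp_relu(tape, tp_linear(tape, Z, pnodes$head$h1))
  pred <- tp_sigmoid(tape, tp_linear(tape, h1, pnodes$head$h2))
  list(pred = pred, attn = if (collect_attn) matrix(at$A, B, dim(at$A)[3]) else NULL)
}

# Assemble the model's input matrices for a set of cells.
#   completer: mkdr_completer used to fill unobserved (teacher) or all
#   (student) CNV/MU from GE; fill: named list(cnv, mu) of mean-fill vectors.
.model_inputs <- function(model, omics, cells, completer = NULL, fill = NULL,
                          use_observed = FALSE) {
  idx <- match(cells, omics$sample_ids)
  if (anyNA(idx)) stop("unknown cell ids: ", paste(cells[is.na(idx)], collapse = ", "))
  obs <- omics$observed[idx, , drop = FALSE]
  ge <- omics$ge[idx, , drop = FALSE]
  if (!all(obs[, "ge"])) stop("gene expression unobserved for cells: ",
                              paste(cells[!obs[, "ge"]], collapse = ", "))
  cnv <- omics$cnv[idx, , drop = FALSE]
  mu <- omics$mu[idx, , drop = FALSE]
  if (model$role == "teacher") {
    need <- !obs[, "cnv"] | !obs[, "mu"]
    if (any(need)) {
      if (!is.null(completer)) {
        comp <- complete(completer, ge[need, , drop = FALSE])
        cnv[need & !obs[, "cnv"], ] <- comp$cnv[(!obs[, "cnv"])[need], , drop = FALSE]
        mu[need & !obs[, "mu"], ] <- comp$mu_prob[(!obs[, "mu"])[need], , drop = FALSE]
      } else if (!is.null(fill)) {
        cnv[!obs[, "cnv"], ] <- matrix(fill$cnv, sum(!obs[, "cnv"]), length(fill$cnv), byrow = TRUE)
        mu[!obs[, "mu"], ] <- matrix(fill$mu, sum(!obs[, "mu"]), length(fill$mu), byrow = TRUE)
      } else {
        stop("teacher given unobserved modality without completion for cells: ",
             paste(cells[need], collapse = ", "))
      }
    }
  } else {
    # student: CNV/MU always pass through the completion (or fill) path so
    # its inputs are well-defined under any missingness pattern
    if (!is.null(completer)) {
      comp <- complete(completer, ge)
      cnv_in <- comp$cnv; mu_in <- comp$mu_prob
    } else if (!is.null(fill)) {
      cnv_in <- matrix(fill$cnv, nrow(ge), length(fill$cnv), byrow = TRUE)
      mu_in <- matrix(fill$mu, nrow(ge), length(fill$mu), byrow = TRUE)
    } else {
      stop("student requires a completer or a mean-fill table for CNV/MU")
    }
    if (use_observed) {
      cnv_in[obs[, "cnv"], ] <- cnv[obs[, "cnv"], , drop = FALSE]
      mu_in[obs[, "mu"], ] <- mu[obs[, "mu"], , drop = FALSE]
    }
    cnv <- cnv_in; mu <- mu_in
  }
  list(ge = unname(ge), cnv = unname(cnv), mu = unname(mu), cells = cells)
}

# build pair-level forward inputs from a bundle view
.pair_inputs <- function(model, bundle, rows, completer = NULL, fill = NULL,
                         use_observed = FALSE) {
  resp <- bundle$responses[rows, , drop = FALSE]
  cells <- sort(unique(resp$cell_id))
  drugs_used <- sort(unique(resp$drug_id))
  om_in <- .model_inputs(model, bundle$omics, cells, completer, fill, use_observed)
  token_mat <- .token_matrix(bundle$drugs)[drugs_used, , drop = FALSE]
  list(ge = om_in$ge, cnv = om_in$cnv, mu = om_in$mu,
       token_mat = token_mat,
       cell_idx = match(resp$cell_id, cells),
       drug_idx = match(resp$drug_id, drugs_used),
       y = resp$y, cells = cells, drugs = drugs_used,
       cell_id = resp$cell_id, drug_id = resp$drug_id)
}

#' Predict scaled drug response for (cell, drug) pairs
#'
#' Runs the network in eval mode (deterministic; identical results for any
#' batch size). Predictions are sigmoid-bounded to (0, 1), matching the
#' scaled response target; use [inverse_response()] for IC50 concentrations.
#'
#' @param object fitted `mkdr_model`.
#' @param bundle dataset bundle (list with `omics`, `drugs`, `responses`).
#' @param pairs data.frame with `cell_id`, `drug_id`; default: all
#'   non-excluded response rows.
#' @param completer optional [fit_vae()] completer (required for a student
#'   unless `fill` is given, and for a teacher facing unobserved
#'   modalities).
#' @param fill optional named list (`cnv`, `mu`) of mean-fill vectors.
#' @param attn return fusion attention weights as an attribute.
#' @param ... unused.
#' @return numeric vector of predictions in (0, 1).
#' @export
predict.mkdr_model <- function(object, bundle, pairs = NULL, completer = NULL,
                               fill = NULL, attn = FALSE, ...) {
  if (is.null(pairs)) {
    rows <- which(bundle$responses$split != "excluded")
  } else {
    key <- paste(bundle$responses$cell_id, bundle$responses$drug_id)
    rows <- match(paste(pairs$cell_id, pairs$drug_id), key)
    if (anyNA(rows)) {
      # pairs not in the response table are still predictable
      return(.predict_pairs(object, bundle, pairs, completer, fill, attn))
    }
  }
  .predict_pairs(object, bundle,
                 bundle$responses[rows, c("cell_id", "drug_id")],
                 completer, fill, attn)
}

.predict_pairs <- function(model, bundle, pairs, completer, fill, attn = FALSE) {
  cells <- sort(unique(pairs$cell_id))
  drugs_used <- sort(unique(pairs$drug_id))
  om_in <- .model_inputs(model, bundle$omics, cells, completer, fill)
  token_mat <- .token_matrix(bundle$drugs)[drugs_used, , drop = FALSE]
  inputs <- list(ge = om_in$ge, cnv = om_in$cnv, mu = om_in$mu,
                 token_mat = token_mat,
                 cell_idx = match(pairs$cell_id, cells),
                 drug_idx = match(pairs$drug_id, drugs_used))
  tape <- tp_new()
  pn <- tp_params(tape, model$params)
  fw <- .mkdr_forward(tape, pn, model, inputs, collect_attn = attn)
  out <- drop(fw$pred$val)
  if (attn) attr(out, "attn") <- fw$attn
  out
}

#' @export
print.mkdr_model <- function(x, ...) {
  cat(sprintf("MKDR %s model (%s)\n", x$role, if (x$trained) "trained" else "untrained"))
  cat(sprintf("  omics: GE %d, CNV %d, MU %d features -> %d tokens x %d dims, %d layers, %d heads\n",
              x$dims$n_ge, x$dims$n_cnv, x$dims$n_mu, x$cfg$n_tokens,
              x$cfg$d_model, x$cfg$n_layers, x$cfg$n_heads))
  cat(sprintf("  drug: vocabulary %d, bi-LSTM hidden %d, %s pooling\n",
              x$dims$vocab_size, x$cfg$d_model %/% 2, x$cfg$pool))
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d epochs; best val MSE %.5f at epoch %d\n",
                nrow(h), min(h$val_mse), which.min(h$val_mse)))
  }
  invisible(x)
}

#' @export
summary.mkdr_model <- function(object, ...) {
  n_par <- sum(vapply(.flatten_params(object$params), length, 1))
  cat(sprintf("MKDR %s model: %d parameters\n", object$role, n_par))
  print(object)
  if (!is.null(object$metrics)) {
    cat("test metrics:\n"); print(object$metrics)
  }
  invisible(object)
}

#' @export
plot.mkdr_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss / val MSE", main = sprintf("MKDR %s training", x$role), ...)
  graphics::lines(h$epoch, h$val_mse, lty = 2)
  graphics::legend("topright", c("training loss", "validation MSE"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
residuals.mkdr_model <- function(object, bundle, split = "test",
                                 completer = NULL, fill = NULL, ...) {
  rows <- which(bundle$responses$split == split)
  pred <- predict(object, bundle, bundle$responses[rows, c("cell_id", "drug_id")],
                  completer = completer, fill = fill)
  bundle$responses$y[rows] - pred
}
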