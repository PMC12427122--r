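# Variational-autoencoder modality completion: infer CNV and mutation
# profiles from gene expression.
#
# The encoder maps GE to a Gaussian posterior q(z | x_ge); the decoder
# reconstructs CNV with a Gaussian likelihood (squared error) and MU with a
# Bernoulli likelihood (binary cross-entropy). Training samples z by
# reparameterisation; inference uses the posterior mean so completion is
# deterministic.

#' VAE completer hyperparameters
#'
#' @param latent_dim latent dimension (>= 1).
#' @param hidden encoder/decoder hidden width.
#' @param kl_weight weight beta on the KL term (>= 0).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param weight_decay decoupled L2 weight decay applied by the optimiser
#'   (regularises the decoder at small sample sizes).
#' @param anneal linearly ramp the KL weight from 0 over the first half of
#'   training.
#' @param seed integer seed.
#' @return list of class `mkdr_vae_config`.
#' @export
vae_config <- function(latent_dim = 16, hidden = 64, kl_weight = 1,
                       lr = 2e-3, epochs = 500, weight_decay = 0.01,
                       anneal = FALSE, seed = 1) {
  stopifnot(latent_dim >= 1, kl_weight >= 0, epochs >= 1)
  structure(list(latent_dim = latent_dim, hidden = hidden,
                 kl_weight = kl_weight, lr = lr, epochs = epochs,
                 weight_decay = weight_decay, anneal = anneal, seed = seed),
            class = "mkdr_vae_config")
}

#' VAE loss components
#'
#' Computes the negative evidence lower bound used for modality completion:
#' Gaussian reconstruction error for CNV (`0.5 * sum of squares`), Bernoulli
#' cross-entropy for MU, and the closed-form KL divergence of the Gaussian
#' posterior from the standard normal prior,
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, all averaged over samples.
#'
#' @param x_cnv,x_mu target matrices (samples x features).
#' @param recon_cnv decoder CNV means, `recon_mu` decoder MU probabilities.
#' @param mu,logvar posterior parameters (samples x latent_dim); `logvar` is
#'   clamped to `[-15, 15]` with a warning on overflow.
#' @param beta KL weight.
#' @return list with `total`, `recon`, `kl`, `recon_cnv`, `recon_mu`.
#' @examples
#' # posterior equal to the prior: KL = 0; mu = 1, var = 1: KL = 0.5
#' vae_loss(matrix(0), matrix(0), matrix(0), matrix(0.5),
#'          mu = matrix(1), logvar = matrix(0), beta = 1)$kl
#' @export
vae_loss <- function(x_cnv, x_mu, recon_cnv, recon_mu, mu, logvar, beta = 1) {
  if (any(abs(logvar) > 15)) {
    warning("log-variance clamped to [-15, 15]")
    logvar <- pmin(pmax(logvar, -15), 15)
  }
  n <- nrow(mu)
  eps <- 1e-12
  rc <- 0.5 * sum((x_cnv - recon_cnv)^2) / n
  rm_ <- -sum(x_mu * log(recon_mu + eps) + (1 - x_mu) * log(1 - recon_mu + eps)) / n
  kl <- 0.5 * sum(mu^2 + exp(logvar) - 1 - logvar) / n
  list(total = rc + rm_ + beta * kl, recon = rc + rm_, kl = kl,
       recon_cnv = rc, recon_mu = rm_)
}

.vae_params_init <- function(n_ge, n_cnv, n_mu, cfg) {
  list(
    enc1 = nn_linear_init(n_ge, cfg$hidden),
    enc_mu = nn_linear_init(cfg$hidden, cfg$latent_dim),
    enc_lv = nn_linear_init(cfg$hidden, cfg$latent_dim),
    dec1 = nn_linear_init(cfg$latent_dim, cfg$hidden),
    dec_cnv = nn_linear_init(cfg$hidden, n_cnv),
    dec_mu = nn_linear_init(cfg$hidden, n_mu)
  )
}

# encoder/decoder graphs
.vae_encode_nodes <- function(tape, x, pn) {
  h <- tp_tanh(tape, tp_linear(tape, x, pn$enc1))
  list(mu = tp_linear(tape, h, pn$enc_mu), logvar = tp_linear(tape, h, pn$enc_lv))
}

.vae_decode_nodes <- function(tape, z, pn) {
  h <- tp_tanh(tape, tp_linear(tape, z, pn$dec1))
  list(cnv = tp_linear(tape, h, pn$dec_cnv),
       mu_prob = tp_sigmoid(tape, tp_linear(tape, h, pn$dec_mu)))
}

#' Fit the VAE modality completer
#'
#' Trains on the cells with all three modalities observed (gene expression
#' as input, CNV and MU as reconstruction targets). Deterministic given the
#' seed.
#'
#' @param omics `mkdr_omics` dataset (or a bundle list with `$omics`).
#' @param cfg [vae_config()].
#' @param min_complete minimum number of fully observed training samples
#'   (default 10).
#' @param holdout_fraction fraction of complete samples held out for the
#'   reconstruction report (0 trains on all).
#' @param verbose print loss every 50 epochs.
#' @return object of class `mkdr_completer` with training history and, when
#'   a holdout was kept, a [evaluate_completion()] report.
#' @export
fit_vae <- function(omics, cfg = vae_config(), min_complete = 10,
                    holdout_fraction = 0, verbose = FALSE) {
  if (!inherits(omics, "mkdr_omics")) omics <- omics$omics
  complete_cells <- which(rowSums(omics$observed) == 3L)
  if (length(complete_cells) == 0) stop("no samples with all three modalities observed")
  if (length(complete_cells) < min_complete) {
    stop(sprintf("need >= %d fully observed samples, have %d", min_complete, length(complete_cells)))
  }
  old <- .seed_swap(cfg$seed)
  on.exit(.seed_restore(old), add = TRUE)
  hold <- integer(0)
  if (holdout_fraction > 0) {
    hold <- sample(complete_cells, max(1, round(holdout_fraction * length(complete_cells))))
  }
  tr <- setdiff(complete_cells, hold)
  ge <- unname(omics$ge[tr, , drop = FALSE])
  cnv <- unname(omics$cnv[tr, , drop = FALSE])
  mu <- unname(omics$mu[tr, , drop = FALSE])
  params <- .vae_params_init(ncol(ge), ncol(cnv), ncol(mu), cfg)
  opt <- adam_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  n <- nrow(ge); k <- cfg$latent_dim
  eps <- 1e-12
  hist <- data.frame(epoch = seq_len(cfg$epochs), total = NA_real_,
                     recon = NA_real_, kl = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    beta <- if (cfg$anneal) cfg$kl_weight * min(1, ep / (cfg$epochs / 2)) else cfg$kl_weight
    tape <- tp_new()
    pn <- tp_params(tape, params)
    xn <- tp_leaf(tape, ge)
    enc <- .vae_encode_nodes(tape, xn, pn)
    noise <- matrix(stats::rnorm(n * k), n, k)
    sd_n <- tp_exp(tape, tp_scale(tape, enc$logvar, 0.5))
    z <- tp_add(tape, enc$mu, tp_mulc(tape, sd_n, noise))
    dec <- .vae_decode_nodes(tape, z, pn)
    # Gaussian NLL for CNV
    l_cnv <- tp_scale(tape, tp_sum(tape, tp_square(tape, tp_sub(tape, dec$cnv, tp_leaf(tape, cnv)))), 0.5 / n)
    # Bernoulli NLL for MU: -[x log p + (1-x) log(1-p)]
    lp <- tp_op(tape, log(dec$mu_prob$val + eps), list(dec$mu_prob),
                function(g, nd) list(g / (nd$parents[[1]]$val + eps)))
    lq <- tp_op(tape, log(1 - dec$mu_prob$val + eps), list(dec$mu_prob),
                function(g, nd) list(-g / (1 - nd$parents[[1]]$val + eps)))
    l_mu <- tp_scale(tape, tp_add(tape, tp_dotc(tape, lp, -mu), tp_dotc(tape, lq, mu - 1)), 1 / n)
    # closed-form KL to N(0, I)
    kl <- tp_scale(tape,
                   tp_sum(tape, tp_sub(tape,
                                       tp_add(tape, tp_square(tape, enc$mu), tp_exp(tape, enc$logvar)),
                                       tp_shift(tape, enc$logvar, 1))),
                   0.5 / n)
    total <- tp_add(tape, tp_add(tape, l_cnv, l_mu), tp_scale(tape, kl, beta))
    tp_backward(tape, total)
    params <- adam_step(opt, params, tp_grads(pn))
    hist[ep, 2:4] <- c(total$val, l_cnv$val + l_mu$val, kl$val)
    if (verbose && ep %% 50 == 0) {
      message(sprintf("vae epoch %d: total %.4f recon %.4f kl %.4f", ep, total$val, l_cnv$val + l_mu$val, kl$val))
    }
  }
  out <- structure(list(params = params, cfg = cfg, trained = TRUE,
                        n_ge = ncol(ge), n_cnv = ncol(cnv), n_mu = ncol(mu),
                        history = hist, train_cells = omics$sample_ids[tr]),
                   class = "mkdr_completer")
  if (length(hold) > 0) {
    out$holdout_report <- evaluate_completion(out, omics, cells = omics$sample_ids[hold])
  }
  out
}

#' Complete CNV and mutation profiles from gene expression
#'
#' Uses the posterior mean (no sampling), so the same GE row always yields
#' the same completion. Mutation outputs are probabilities in `[0, 1]`;
#' binarise at 0.5 only where a downstream consumer requires binary calls.
#'
#' @param completer fitted `mkdr_completer`.
#' @param ge numeric matrix (samples x n_ge) or a single row vector.
#' @param sample draw a latent sample instead of the posterior mean
#'   (non-deterministic; off by default).
#' @return list with `cnv` (continuous matrix) and `mu_prob` (probability
#'   matrix).
#' @export
complete <- function(completer, ge, sample = FALSE) {
  if (!inherits(completer, "mkdr_completer") || !isTRUE(completer$trained)) {
    stop("completer is not a trained mkdr_completer")
  }
  if (is.null(dim(ge))) ge <- matrix(ge, 1)
  if (ncol(ge) != completer$n_ge) stop("GE width mismatch")
  if (anyNA(ge)) stop("GE row unobserved (contains NA)")
  tape <- tp_new()
  pn <- tp_params(tape, completer$params)
  enc <- .vae_encode_nodes(tape, tp_leaf(tape, unname(ge)), pn)
  zval <- enc$mu$val
  if (sample) zval <- zval + exp(enc$logvar$val / 2) * matrix(stats::rnorm(length(zval)), nrow(zval))
  dec <- .vae_decode_nodes(tape, tp_leaf(tape, zval), pn)
  list(cnv = dec$cnv$val, mu_prob = dec$mu_prob$val)
}

#' @export
predict.mkdr_completer <- function(object, ge, ...) complete(object, ge)

#' @export
print.mkdr_completer <- function(x, ...) {
  cat(sprintf("VAE modality completer: GE(%d) -> CNV(%d) + MU(%d), latent %d\n",
              x$n_ge, x$n_cnv, x$n_mu, x$cfg$latent_dim))
  cat(sprintf("  trained %d epochs on %d complete samples; final loss %.4f\n",
              nrow(x$history), length(x$train_cells), x$history$total[nrow(x$history)]))
  invisible(x)
}

#' @export
plot.mkdr_completer <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$total, type = "l",
                 xlab = "epoch", ylab = "loss", main = "VAE completion training", ...)
  invisible(x)
}

#' Evaluate completion quality against held-out truth
#'
#' Per-feature PCC, R2, MSE and MAE for CNV; per-feature AUROC for MU
#' (features without both classes in the evaluation cells are flagged
#' undefined), plus aggregates.
#'
#' @param completer fitted `mkdr_completer`.
#' @param omics `mkdr_omics` with true CNV/MU for the evaluation cells.
#' @param cells cell ids to evaluate (default: all cells with all three
#'   modalities observed that were not used in training).
#' @return object of class `mkdr_completion_report`: list with `cnv`
#'   (per-feature data.frame), `mu` (per-feature data.frame), `summary`.
#' @export
evaluate_completion <- function(completer, omics, cells = NULL) {
  if (!inherits(omics, "mkdr_omics")) omics <- omics$omics
  if (is.null(cells)) {
    cells <- setdiff(omics$sample_ids[rowSums(omics$observed) == 3L],
                     completer$train_cells)
  }
  idx <- match(cells, omics$sample_ids)
  if (length(idx) == 0) stop("no evaluation cells")
  ge <- omics$ge[idx, , drop = FALSE]
  cnv <- omics$cnv[idx, , drop = FALSE]
  mu <- omics$mu[idx, , drop = FALSE]
  comp <- complete(completer, ge)
  cnv_tab <- data.frame(
    feature = colnames(cnv),
    PCC = vapply(seq_len(ncol(cnv)), function(j) {
      if (stats::sd(cnv[, j]) == 0 || stats::sd(comp$cnv[, j]) == 0) NA_real_
      else stats::cor(cnv[, j], comp$cnv[, j])
    }, 1),
    R2 = vapply(seq_len(ncol(cnv)), function(j) {
      ss <- sum((cnv[, j] - mean(cnv[, j]))^2)
      if (ss == 0) NA_real_ else 1 - sum((cnv[, j] - comp$cnv[, j])^2) / ss
    }, 1),
    MSE = colMeans((cnv - comp$cnv)^2),
    MAE = colMeans(abs(cnv - comp$cnv)),
    stringsAsFactors = FALSE
  )
  mu_tab <- data.frame(
    feature = colnames(mu),
    AUROC = vapply(seq_len(ncol(mu)), function(j) .auroc(mu[, j], comp$mu_prob[, j]), 1),
    positives = colSums(mu),
    stringsAsFactors = FALSE
  )
  mu_tab$undefined <- is.na(mu_tab$AUROC)
  structure(list(
    cnv = cnv_tab, mu = mu_tab, n_cells = length(idx),
    summary = c(cnv_pcc_mean = mean(cnv_tab$PCC, na.rm = TRUE),
                cnv_r2_mean = mean(cnv_tab$R2, na.rm = TRUE),
                cnv_mse_mean = mean(cnv_tab$MSE),
                cnv_mae_mean = mean(cnv_tab$MAE),
                mu_auroc_mean = mean(mu_tab$AUROC, na.rm = TRUE))
  ), class = "mkdr_completion_report")
}

#' @export
print.mkdr_completion_report <- function(x, ...) {
  cat(sprintf("Completion report over %d cells\n", x$n_cells))
  print(round(x$summary, 4))
  cat(sprintf("  MU features with undefined AUROC: %d of %d\n",
              sum(x$mu$undefined), nrow(x$mu)))
  invisible(x)
}

# training-set feature means over observed cells, the no-completion baseline
.mean_fill <- function(omics, cells = NULL) {
  if (is.null(cells)) cells <- omics$sample_ids
  idx <- match(cells, omics$sample_ids)
  list(
    cnv = colMeans(omics$cnv[idx[omics$observed[idx, "cnv"]], , drop = FALSE]),
    mu = colMeans(omics$mu[idx[omics$observed[idx, "mu"]], , drop = FALSE])
  )
}
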