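# Seeded synthetic multi-omics / drug / response generator.
#
# A shared low-dimensional cell-line state drives all three omics layers, so
# CNV and mutation are recoverable from gene expression — the cross-modal
# dependence the completion model is meant to learn. Drugs are token
# sequences over a SMILES-like alphabet whose token composition determines a
# drug latent, so the sequence encoder can learn it. The response surface is
# a bilinear cell x drug interaction plus a mild quadratic term, squashed
# into (0, 1) and observed as log-scale IC50 with noise.

.SIM_ALPHABET <- c("C", "c", "N", "n", "O", "o", "S", "s", "F", "Cl", "Br",
                   "P", "(", ")", "=", "#", "1", "2", "3", "[nH]", "[O-]", "[N+]")

#' Configuration for the synthetic data generator
#'
#' Defaults are desk-scale: 60 cell lines, 40 drugs, 200 GE / 60 CNV / 80 MU
#' features over an 8-dimensional latent state, preserving the GE >> CNV/MU
#' dimensional ordering of real cell-line panels at a size that trains in
#' minutes on one CPU.
#'
#' @param n_cells,n_drugs,n_ge,n_cnv,n_mu,latent_dim counts (all >= 1).
#' @param noise_sd named per-modality observation noise SD (for MU it acts on
#'   the logit scale).
#' @param response_noise_sd SD of the noise added to log-IC50.
#' @param missing_rate named per-modality probability that a sample's
#'   modality is unobserved.
#' @param mutation_rate_target mean mutation rate in (0, 1); the logit
#'   intercept is calibrated to hit it.
#' @param quad_coef weight of the quadratic interaction in the response.
#' @param ic50_scale multiplier mapping the (0,1) response onto log-IC50.
#' @param pair_fraction fraction of the cell x drug grid with measured
#'   responses.
#' @param smiles_len_range integer range of drug token-sequence lengths.
#' @param seed integer seed; the whole output is reproducible from it.
#' @return list of class `mkdr_sim_config`.
#' @export
sim_config <- function(n_cells = 60, n_drugs = 40, n_ge = 200, n_cnv = 60,
                       n_mu = 80, latent_dim = 8,
                       noise_sd = c(ge = 0.05, cnv = 0.05, mu = 0),
                       response_noise_sd = 0.1,
                       missing_rate = c(ge = 0, cnv = 0, mu = 0),
                       mutation_rate_target = 0.15,
                       quad_coef = 0.3, ic50_scale = 3, pair_fraction = 1,
                       smiles_len_range = c(8, 20), seed = 1) {
  counts <- c(n_cells, n_drugs, n_ge, n_cnv, n_mu, latent_dim)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (latent_dim > min(n_ge, n_cnv, n_mu)) stop("latent_dim exceeds a feature count")
  stopifnot(all(missing_rate >= 0 & missing_rate <= 1),
            mutation_rate_target > 0, mutation_rate_target < 1,
            all(noise_sd >= 0), response_noise_sd >= 0,
            pair_fraction > 0, pair_fraction <= 1)
  structure(list(n_cells = n_cells, n_drugs = n_drugs, n_ge = n_ge,
                 n_cnv = n_cnv, n_mu = n_mu, latent_dim = latent_dim,
                 noise_sd = noise_sd, response_noise_sd = response_noise_sd,
                 missing_rate = missing_rate,
                 mutation_rate_target = mutation_rate_target,
                 quad_coef = quad_coef, ic50_scale = ic50_scale,
                 pair_fraction = pair_fraction,
                 smiles_len_range = smiles_len_range, seed = seed),
            class = "mkdr_sim_config")
}

#' Generate a synthetic multi-omics drug response dataset
#'
#' See [sim_config()] for the generative model. Returns the omics dataset
#' (with modality-level missingness applied as NA rows plus mask), a drug
#' library, raw (cell, drug, IC50) response triples, and the generative
#' truth (latents, loadings, interaction weights, noiseless responses) for
#' parameter-recovery tests.
#'
#' @param config `mkdr_sim_config`.
#' @return list with `omics`, `drugs`, `responses_raw` (data.frame),
#'   `truth`.
#' @export
simulate_mkdr <- function(config = sim_config()) {
  cf <- config
  old <- .seed_swap(cf$seed)
  on.exit(.seed_restore(old), add = TRUE)
  k <- cf$latent_dim
  cell_ids <- sprintf("CELL%03d", seq_len(cf$n_cells))
  drug_ids <- sprintf("DRUG%03d", seq_len(cf$n_drugs))

  H <- matrix(stats::rnorm(cf$n_cells * k), cf$n_cells, k)
  A_ge <- matrix(stats::rnorm(cf$n_ge * k, sd = 1 / sqrt(k)), cf$n_ge, k)
  A_cnv <- matrix(stats::rnorm(cf$n_cnv * k, sd = 1 / sqrt(k)), cf$n_cnv, k)
  # mutation loadings are stronger than the continuous ones so that the
  # latent state separates carriers well (latent-based AUROC >~ 0.9)
  A_mu <- matrix(stats::rnorm(cf$n_mu * k, sd = 4 / sqrt(k)), cf$n_mu, k)

  ge <- H %*% t(A_ge) + matrix(stats::rnorm(cf$n_cells * cf$n_ge, sd = cf$noise_sd[["ge"]]), cf$n_cells)
  cnv <- H %*% t(A_cnv) + matrix(stats::rnorm(cf$n_cells * cf$n_cnv, sd = cf$noise_sd[["cnv"]]), cf$n_cells)
  logits <- H %*% t(A_mu)
  if (cf$noise_sd[["mu"]] > 0) {
    logits <- logits + matrix(stats::rnorm(length(logits), sd = cf$noise_sd[["mu"]]), nrow(logits))
  }
  # calibrate the intercept so the mean mutation rate hits the target
  b_mu <- stats::uniroot(function(b) mean(stats::plogis(logits + b)) - cf$mutation_rate_target,
                         interval = c(-30, 30))$root
  mu_prob <- stats::plogis(logits + b_mu)
  mu <- matrix(stats::rbinom(length(mu_prob), 1, mu_prob), nrow(mu_prob))

  dimnames(ge) <- list(cell_ids, sprintf("GE%04d", seq_len(cf$n_ge)))
  dimnames(cnv) <- list(cell_ids, sprintf("CNV%04d", seq_len(cf$n_cnv)))
  dimnames(mu) <- list(cell_ids, sprintf("MU%04d", seq_len(cf$n_mu)))

  # drugs: token sequences; the drug latent is a projection of token counts
  lens <- sample(cf$smiles_len_range[1]:cf$smiles_len_range[2], cf$n_drugs, replace = TRUE)
  seqs <- lapply(lens, function(L) sample(.SIM_ALPHABET, L, replace = TRUE))
  smiles <- vapply(seqs, paste0, "", collapse = "")
  V <- length(.SIM_ALPHABET)
  counts <- t(vapply(seqs, function(s) {
    tabulate(match(s, .SIM_ALPHABET), nbins = V)
  }, numeric(V)))
  P <- matrix(stats::rnorm(V * k, sd = 1 / sqrt(V)), V, k)
  G <- scale(counts %*% P)
  attr(G, "scaled:center") <- NULL; attr(G, "scaled:scale") <- NULL
  G <- matrix(as.numeric(G), cf$n_drugs, k, dimnames = list(drug_ids, NULL))

  # response surface: bilinear + mild quadratic interaction, squashed to (0,1)
  W <- matrix(stats::rnorm(k * k, sd = 1 / sqrt(k)), k, k)
  W2 <- matrix(stats::rnorm(k * k, sd = 1 / sqrt(k)), k, k)
  lin <- H %*% W %*% t(G)
  qd <- (H %*% W2 %*% t(G))^2
  s <- lin + cf$quad_coef * qd
  s_std <- (s - mean(s)) / stats::sd(s)
  f <- stats::plogis(s_std)

  pairs <- expand.grid(cell_id = cell_ids, drug_id = drug_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (cf$pair_fraction < 1) {
    keep <- sort(sample(nrow(pairs), ceiling(cf$pair_fraction * nrow(pairs))))
    pairs <- pairs[keep, , drop = FALSE]
  }
  ci <- match(pairs$cell_id, cell_ids)
  di <- match(pairs$drug_id, drug_ids)
  f_pair <- f[cbind(ci, di)]
  log_ic50 <- cf$ic50_scale * f_pair + stats::rnorm(nrow(pairs), sd = cf$response_noise_sd)
  responses_raw <- data.frame(pairs, ic50 = exp(log_ic50), stringsAsFactors = FALSE)

  # modality-level missingness: whole (sample, modality) rows
  obs <- matrix(TRUE, cf$n_cells, 3, dimnames = list(cell_ids, c("ge", "cnv", "mu")))
  ge_obs <- ge; cnv_obs <- cnv; mu_obs <- mu
  for (m in c("ge", "cnv", "mu")) {
    rate <- cf$missing_rate[[m]]
    if (rate > 0) {
      miss <- stats::runif(cf$n_cells) < rate
      obs[miss, m] <- FALSE
      if (m == "ge") ge_obs[miss, ] <- NA
      if (m == "cnv") cnv_obs[miss, ] <- NA
      if (m == "mu") mu_obs[miss, ] <- NA
    }
  }

  omics <- omics_dataset(ge_obs, cnv_obs, mu_obs, observed = obs)
  drugs <- drug_library(drug_ids, smiles, max_len = cf$smiles_len_range[2])
  truth <- list(H = H, A_ge = A_ge, A_cnv = A_cnv, A_mu = A_mu, b_mu = b_mu,
                G = G, W = W, W2 = W2, P = P,
                f = f, noiseless = f_pair,
                ge_full = ge, cnv_full = cnv, mu_full = mu,
                mu_prob = mu_prob, config = cf)
  list(omics = omics, drugs = drugs, responses_raw = responses_raw, truth = truth)
}

#' Plant response outliers beyond the IQR fences
#'
#' Shifts `n_outliers` randomly chosen rows of a raw response table so their
#' log-IC50 lies `magnitude * IQR` beyond the fence (alternating sides). Used
#' to test that the IQR exclusion rule removes exactly the planted rows.
#'
#' @param responses_raw data.frame with `ic50` (and id columns).
#' @param n_outliers number of rows to shift (must be `< nrow/10`).
#' @param magnitude fence overshoot in IQR units; with
#'   `magnitude > iqr_factor` recomputed fences still exclude the planted
#'   rows. `0` leaves values at the fence (nothing new excluded).
#' @param iqr_factor fence multiplier the downstream rule will use.
#' @param seed integer seed.
#' @return the table with shifted `ic50`; planted row indices in
#'   `attr(, "planted")`.
#' @export
plant_outliers <- function(responses_raw, n_outliers, magnitude = 3,
                           iqr_factor = 1.5, seed = 1) {
  n <- nrow(responses_raw)
  if (n_outliers >= n / 10) stop("n_outliers must be below a tenth of the rows")
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old), add = TRUE)
  y <- log(responses_raw$ic50)
  q <- stats::quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  rows <- sample(n, n_outliers)
  side <- rep_len(c(1, -1), n_outliers)
  fence <- ifelse(side > 0, q[2] + iqr_factor * iqr, q[1] - iqr_factor * iqr)
  y[rows] <- fence + side * magnitude * iqr
  responses_raw$ic50[rows] <- exp(y[rows])
  attr(responses_raw, "planted") <- sort(rows)
  responses_raw
}
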