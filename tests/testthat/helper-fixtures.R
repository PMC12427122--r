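# Shared fixtures, memoised so expensive objects (simulated bundles, trained
# models) are built once per test run. A small encoder configuration keeps
# training inside seconds while exercising every architectural component.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

light_cfg <- function() {
  encoder_config(d_model = 16, n_heads = 2, n_layers = 1, n_tokens = 8,
                 head_hidden = 16)
}

# default-condition synthetic bundle, split with seed 11
fixture_bundle <- function() {
  memo("bundle", function() {
    sim <- simulate_mkdr(sim_config(seed = 1))
    resp <- make_split(preprocess_responses(sim$responses_raw), seed = 11)
    list(omics = sim$omics, drugs = sim$drugs, responses = resp,
         truth = sim$truth)
  })
}

# tiny bundle for fast structural tests (few cells/drugs/features)
tiny_bundle <- function() {
  memo("tiny", function() {
    sim <- simulate_mkdr(sim_config(n_cells = 20, n_drugs = 8, n_ge = 40,
                                    n_cnv = 16, n_mu = 20, latent_dim = 4,
                                    smiles_len_range = c(6, 10), seed = 5))
    resp <- make_split(preprocess_responses(sim$responses_raw), seed = 5)
    list(omics = sim$omics, drugs = sim$drugs, responses = resp,
         truth = sim$truth)
  })
}

# briefly trained teacher on the tiny bundle (structure and gradients sound,
# not converged)
fixture_teacher <- function() {
  memo("teacher", function() {
    train_teacher(tiny_bundle(), cfg = light_cfg(), epochs = 15, lr = 5e-3,
                  patience = 15, seed = 2)
  })
}

fixture_completer <- function() {
  memo("completer", function() {
    fit_vae(tiny_bundle()$omics, vae_config(epochs = 120, seed = 2))
  })
}

fixture_student <- function() {
  memo("student", function() {
    train_student(tiny_bundle(), teacher = fixture_teacher(),
                  completer = fixture_completer(), kd = kd_config(),
                  cfg = light_cfg(), epochs = 15, lr = 5e-3, patience = 15,
                  seed = 2)
  })
}

# independent brute-force metric implementations (explicit summation
# formulas; ranks by sorting) used as oracles against compute_metrics()
brute_metrics <- function(y, p) {
  n <- length(y)
  mse <- sum((p - y)^2) / n
  mae <- sum(abs(p - y)) / n
  my <- sum(y) / n; mp <- sum(p) / n
  sstot <- sum((y - my)^2)
  r2 <- 1 - sum((p - y)^2) / sstot
  pcc <- sum((y - my) * (p - mp)) / sqrt(sum((y - my)^2) * sum((p - mp)^2))
  rk <- function(v) {
    o <- order(v)
    r <- numeric(n)
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  ry <- rk(y); rp <- rk(p)
  mry <- mean(ry); mrp <- mean(rp)
  scc <- sum((ry - mry) * (rp - mrp)) / sqrt(sum((ry - mry)^2) * sum((rp - mrp)^2))
  list(MSE = mse, RMSE = sqrt(mse), MAE = mae, R2 = r2, PCC = pcc, SCC = scc)
}

# brute-force AUROC via pairwise comparisons
brute_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}
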