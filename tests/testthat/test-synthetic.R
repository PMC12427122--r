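# Statistical structure of the synthetic generator: cross-modal
# recoverability, calibrated mutation rate, solvable response surface,
# reproducibility, and outlier planting.

test_that("same seed gives bit-identical output, different seeds differ", {
  cf <- sim_config(n_cells = 15, n_drugs = 6, n_ge = 30, n_cnv = 10,
                   n_mu = 12, latent_dim = 4, seed = 42)
  a <- simulate_mkdr(cf)
  b <- simulate_mkdr(cf)
  expect_identical(a$omics$ge, b$omics$ge)
  expect_identical(a$omics$mu, b$omics$mu)
  expect_identical(a$responses_raw, b$responses_raw)
  expect_identical(a$drugs$smiles, b$drugs$smiles)
  cf2 <- cf; cf2$seed <- 43
  expect_false(identical(simulate_mkdr(cf2)$omics$ge, a$omics$ge))
})

test_that("degenerate configuration is rejected", {
  expect_error(sim_config(n_cnv = 4, latent_dim = 8), "latent_dim")
  expect_error(sim_config(mutation_rate_target = 0), "mutation_rate_target")
})

test_that("CNV is linearly recoverable from GE through the shared latent", {
  sim <- simulate_mkdr(sim_config(noise_sd = c(ge = 0, cnv = 0, mu = 0),
                                  seed = 3))
  ge <- cbind(1, sim$omics$ge)
  r2 <- vapply(seq_len(ncol(sim$omics$cnv)), function(j) {
    y <- sim$omics$cnv[, j]
    fit <- lm.fit(ge, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }, 1)
  expect_true(all(r2 >= 0.99))
})

test_that("mutation intercept calibration hits the target rate", {
  # large sample so the Monte-Carlo rate concentrates
  sim <- simulate_mkdr(sim_config(n_cells = 400, n_drugs = 5, n_ge = 50,
                                  n_cnv = 20, n_mu = 200, latent_dim = 6,
                                  mutation_rate_target = 0.1, seed = 9))
  expect_lt(abs(mean(sim$omics$mu) - 0.1), 0.02)
  sim2 <- simulate_mkdr(sim_config(n_cells = 400, n_drugs = 5, n_ge = 50,
                                   n_cnv = 20, n_mu = 200, latent_dim = 6,
                                   mutation_rate_target = 0.3, seed = 9))
  expect_lt(abs(mean(sim2$omics$mu) - 0.3), 0.02)
})

test_that("latent state separates mutation carriers (cross-modal signal)", {
  sim <- simulate_mkdr(sim_config(seed = 2))
  # logit of the true mutation probability is the latent-based score
  p <- sim$truth$mu_prob
  y <- sim$truth$mu_full
  au <- vapply(seq_len(ncol(y)), function(j) {
    if (length(unique(y[, j])) < 2) return(NA_real_)
    brute_auroc(y[, j], p[, j])
  }, 1)
  expect_gt(mean(au, na.rm = TRUE), 0.9)
})

test_that("modality-level missingness is Bernoulli at the configured rate", {
  rate <- 0.3
  sims <- lapply(1:10, function(s) {
    simulate_mkdr(sim_config(n_cells = 400, n_drugs = 5, n_ge = 20,
                             n_cnv = 10, n_mu = 10, latent_dim = 4,
                             missing_rate = c(ge = 0, cnv = rate, mu = rate),
                             seed = s))
  })
  # pooled over independent draws so the 2-SE band is a meaningful check
  n <- 400 * length(sims)
  se <- sqrt(rate * (1 - rate) / n)
  for (m in c("cnv", "mu")) {
    emp <- mean(vapply(sims, function(s) mean(!s$omics$observed[, m]), 1))
    expect_lt(abs(emp - rate), 2 * se + 1e-9)
  }
  # unobserved rows carry NA, never silent zeros
  sim <- sims[[1]]
  miss <- !sim$omics$observed[, "cnv"]
  expect_true(all(is.na(sim$omics$cnv[miss, ])))
})

test_that("the response surface is solvable from the generative truths", {
  sim <- simulate_mkdr(sim_config(seed = 1, response_noise_sd = 0))
  tr <- sim$truth
  pairs <- sim$responses_raw
  ci <- match(pairs$cell_id, sim$omics$sample_ids)
  di <- match(pairs$drug_id, sim$drugs$drug_ids)
  H <- tr$H[ci, ]; G <- tr$G[di, ]
  X <- cbind(1,
             t(vapply(seq_len(nrow(H)), function(r) c(outer(H[r, ], G[r, ])),
                      numeric(ncol(H) * ncol(G)))),
             rowSums((H %*% tr$W2) * G)^2)
  f <- tr$noiseless
  # linear on the known link scale, fit on half, scored on the other half
  idx <- seq_len(nrow(X)) %% 2 == 0
  beta <- qr.coef(qr(X[idx, ]), qlogis(f[idx]))
  pred <- plogis(drop(X[!idx, ] %*% beta))
  r2 <- 1 - sum((f[!idx] - pred)^2) / sum((f[!idx] - mean(f[!idx]))^2)
  expect_gte(r2, 0.95)
})

test_that("planted outliers are exactly the rows the IQR rule removes", {
  # base table with uniform log-IC50: the fences sit beyond the data range,
  # so the only exclusions are the planted ones
  set.seed(8)
  raw <- data.frame(cell_id = rep(sprintf("c%02d", 1:20), 10),
                    drug_id = rep(sprintf("d%02d", 1:10), each = 20),
                    ic50 = exp(runif(200, 0, 3)))
  expect_equal(sum(preprocess_responses(raw)$split == "excluded"), 0)

  planted <- plant_outliers(raw, n_outliers = 5, magnitude = 3, seed = 21)
  ids <- attr(planted, "planted")
  expect_length(ids, 5)
  tab <- preprocess_responses(planted, iqr_factor = 1.5)
  expect_identical(which(tab$split == "excluded"), ids)

  # magnitude 0 leaves the planted rows at the fence: nothing excluded
  at_fence <- plant_outliers(raw, n_outliers = 5, magnitude = 0, seed = 21)
  expect_equal(sum(preprocess_responses(at_fence)$split == "excluded"), 0)

  # precondition: too many outliers for the table size
  expect_error(plant_outliers(raw[1:9, ], n_outliers = 1), "below a tenth")
})
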