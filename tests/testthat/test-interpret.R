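# Integrated-gradients axioms, modality shares and feature ranking.

test_that("a linear model is attributed exactly at any step count", {
  set.seed(1)
  w <- rnorm(12); x <- rnorm(12); b <- rnorm(12)
  gf <- function(X) list(grad = matrix(w, nrow(X), 12, byrow = TRUE),
                         value = drop(X %*% w))
  for (steps in c(8, 32, 128)) {
    r <- ig_path_attributions(gf, x, b, steps = steps)
    expect_equal(r$attributions, w * (x - b), tolerance = 1e-12)
    expect_lt(r$completeness_gap, 1e-10)
  }
  # input equal to the baseline: all attributions vanish
  r0 <- ig_path_attributions(gf, b, b, steps = 8)
  expect_true(all(r0$attributions == 0))
  expect_error(ig_path_attributions(gf, x, b, steps = 4), "steps")
  expect_error(ig_path_attributions(gf, x, b[-1], steps = 8), "shape")
})

test_that("model attributions satisfy completeness and converge with steps", {
  te <- fixture_teacher()
  b <- tiny_bundle()
  pair <- b$responses[b$responses$split == "test", ][2, ]
  a64 <- integrated_gradients(te, b, pair$cell_id, pair$drug_id, steps = 64)
  a256 <- integrated_gradients(te, b, pair$cell_id, pair$drug_id, steps = 256)
  a1024 <- integrated_gradients(te, b, pair$cell_id, pair$drug_id, steps = 1024)
  # f(x) from the attribution pass equals the model prediction
  expect_equal(a64$f_x,
               unname(predict(te, b, pair[, c("cell_id", "drug_id")])),
               tolerance = 1e-10)
  # the gap shrinks with the step count (left-Riemann convergence)
  expect_lte(a256$completeness_gap, 4 * a1024$completeness_gap + 1e-12)
  expect_lt(a1024$completeness_gap, a64$completeness_gap + 1e-12)
})

test_that("modality shares normalise to 100% and flag degenerate inputs", {
  a <- structure(list(ge = c(f1 = 0.2, f2 = -0.3), cnv = c(c1 = 0, c2 = 0),
                      mu = c(m1 = 0, m2 = 0), drug = c(C = 9)),
                 class = "mkdr_attribution")
  sh <- modality_shares(a)
  expect_equal(as.numeric(sh), c(100, 0, 0)) # drug excluded from denominator
  expect_equal(sum(sh), 100, tolerance = 1e-6)
  a0 <- a; a0$ge[] <- 0
  expect_true(attr(modality_shares(a0), "undefined"))
})

test_that("top features rank by magnitude with deterministic tie-breaks", {
  a <- structure(list(ge = c(g_b = 0.5, g_a = -0.5, g_c = 0.1),
                      cnv = c(c1 = 0.9), mu = c(m1 = 0.2)),
                 class = "mkdr_attribution")
  tf <- top_features(a, k = 3)
  expect_equal(tf$feature, c("c1", "g_a", "g_b")) # |0.9|, then ties by name
  expect_equal(tf$modality[1], "CNV")
  expect_warning(tf_all <- top_features(a, k = 10), "truncated")
  expect_equal(nrow(tf_all), 5)
  # permuting feature order leaves the ranking content unchanged
  a_perm <- a; a_perm$ge <- a$ge[c(3, 1, 2)]
  expect_equal(top_features(a_perm, k = 3)$feature, tf$feature)
})

test_that("a planted dominant feature ranks first", {
  set.seed(2)
  w <- rnorm(30, sd = 0.1); w[17] <- 5 # dominant loading
  x <- rnorm(30); b <- rep(0, 30)
  gf <- function(X) list(grad = matrix(w, nrow(X), 30, byrow = TRUE),
                         value = drop(X %*% w))
  att <- ig_path_attributions(gf, x, b, steps = 16)$attributions
  names(att) <- sprintf("g%02d", 1:30)
  a <- structure(list(ge = att, cnv = NULL, mu = NULL),
                 class = "mkdr_attribution")
  expect_equal(top_features(a, k = 1)$feature, "g17")
})

test_that("student attributions keep nonzero shares on completed modalities", {
  st <- fixture_student()
  b <- tiny_bundle()
  comp <- fixture_completer()
  pairs <- b$responses[b$responses$split == "test", ][1:3, c("cell_id", "drug_id")]
  aset <- attribute_set(st, b, pairs, steps = 16, completer = comp,
                        mode = "completed")
  sh <- modality_shares(aset)
  expect_false(attr(sh, "undefined"))
  expect_gt(sh[["cnv"]], 0)
  expect_gt(sh[["mu"]], 0)
  expect_equal(sum(sh), 100, tolerance = 1e-6)
  tf <- top_features(aset, k = 5)
  expect_equal(nrow(tf), 5)
  expect_true(all(tf$modality %in% c("GE", "CNV", "MU")))
})

test_that("end-to-end gradients through the completer attribute raw GE", {
  st <- fixture_student()
  b <- tiny_bundle()
  comp <- fixture_completer()
  pair <- b$responses[b$responses$split == "test", ][1, ]
  ag <- integrated_gradients(st, b, pair$cell_id, pair$drug_id, steps = 16,
                             completer = comp, mode = "ge_only")
  expect_null(ag$cnv)
  expect_null(ag$mu)
  expect_length(ag$ge, ncol(b$omics$ge))
  expect_true(any(ag$ge != 0))
  expect_error(integrated_gradients(st, b, pair$cell_id, pair$drug_id,
                                    steps = 16, mode = "ge_only"),
               "requires the completer")
})
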