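# Omics loading, IC50 preprocessing, splitting and bundle round-trips.

write_omics_csv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

toy_mats <- function(ids = c("A", "B", "C", "D")) {
  ge <- matrix(rnorm(length(ids) * 3), length(ids), 3,
               dimnames = list(ids, c("g1", "g2", "g3")))
  cnv <- matrix(rnorm(length(ids) * 2), length(ids), 2,
                dimnames = list(ids, c("c1", "c2")))
  mu <- matrix(rbinom(length(ids) * 2, 1, 0.3), length(ids), 2,
               dimnames = list(ids, c("m1", "m2")))
  list(ge = ge, cnv = cnv, mu = mu)
}

test_that("load_omics round-trips toy files and intersects sample sets", {
  set.seed(1)
  m <- toy_mats()
  d <- withr::local_tempdir()
  paths <- list(ge = write_omics_csv(m$ge, file.path(d, "ge.csv")),
                cnv = write_omics_csv(m$cnv, file.path(d, "cnv.csv")),
                mu = write_omics_csv(m$mu, file.path(d, "mu.csv")))
  om <- load_omics(paths)
  expect_equal(length(om$sample_ids), 4)
  expect_true(all(om$observed))
  expect_equal(unname(om$ge), unname(m$ge))

  # GE only: other modalities flagged unobserved, not zero-filled
  om_ge <- load_omics(list(ge = paths$ge, cnv = NULL, mu = NULL))
  expect_true(all(om_ge$observed[, "ge"]))
  expect_false(any(om_ge$observed[, "cnv"]))
  expect_false(any(om_ge$observed[, "mu"]))
  expect_equal(ncol(om_ge$cnv), 0)

  # sample set intersection: GE has A,B,C; CNV has B,C,D -> dataset over B,C
  m2 <- toy_mats(c("B", "C", "D"))
  p_ge_abc <- write_omics_csv(m$ge[c("A", "B", "C"), ], file.path(d, "ge2.csv"))
  p_cnv_bcd <- write_omics_csv(m2$cnv, file.path(d, "cnv2.csv"))
  om2 <- load_omics(list(ge = p_ge_abc, cnv = p_cnv_bcd, mu = NULL))
  expect_setequal(om2$sample_ids, c("B", "C"))
})

test_that("omics invariants are enforced", {
  set.seed(2)
  m <- toy_mats()
  # duplicate sample ids
  bad <- m$ge; rownames(bad) <- c("A", "A", "B", "C")
  expect_error(omics_dataset(bad, m$cnv, m$mu), "duplicate sample ids")
  # non-binary mutation values name the offending cell
  mu_bad <- m$mu; mu_bad["B", "m2"] <- 0.5
  expect_error(omics_dataset(m$ge, m$cnv, mu_bad), "non-binary.*B.*m2")
  # duplicate feature names
  ge_bad <- m$ge; colnames(ge_bad) <- c("g1", "g1", "g3")
  expect_error(omics_dataset(ge_bad, m$cnv, m$mu), "unique feature names")
})

test_that("IQR rule excludes exactly the fence-violating rows and scales to [0,1]", {
  # log-IC50 values 1..9 plus 100: fences from linear-interpolation quartiles
  raw <- data.frame(cell_id = paste0("c", 1:10), drug_id = "d1",
                    ic50 = exp(c(1:9, 100)))
  tab <- preprocess_responses(raw, iqr_factor = 1.5)
  q <- quantile(c(1:9, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(attr(tab, "scaling")$fence_lo, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(attr(tab, "scaling")$fence_hi, q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(sum(tab$split == "excluded"), 1)
  expect_equal(tab$exclude_reason[10], "iqr_outlier")
  # min and max surviving values map exactly to 0 and 1
  kept <- tab$y[tab$split != "excluded"]
  expect_equal(min(kept), 0)
  expect_equal(max(kept), 1)
  # inverse transform recovers the surviving concentrations
  expect_equal(inverse_response(kept, attr(tab, "scaling")),
               raw$ic50[1:9], tolerance = 1e-12)
})

test_that("preprocessing rejects degenerate inputs", {
  expect_error(preprocess_responses(
    data.frame(cell_id = "a", drug_id = "d", ic50 = -1)), "nonpositive")
  expect_error(preprocess_responses(
    data.frame(cell_id = c("a", "a"), drug_id = c("d", "d"), ic50 = c(1, 2))),
    "duplicate")
  # all values equal: IQR 0, nothing excluded, but scaling impossible
  expect_error(preprocess_responses(
    data.frame(cell_id = paste0("c", 1:5), drug_id = "d", ic50 = rep(2, 5))),
    "zero range")
})

test_that("IQR exclusion is idempotent under frozen fences", {
  set.seed(3)
  raw <- data.frame(cell_id = paste0("c", 1:200), drug_id = "d1",
                    ic50 = exp(c(rnorm(195), 8, 9, -8, 10, -9)))
  tab <- preprocess_responses(raw)
  sc <- attr(tab, "scaling")
  kept <- tab[tab$split != "excluded", ]
  tab2 <- preprocess_responses(
    data.frame(cell_id = kept$cell_id, drug_id = kept$drug_id, ic50 = kept$y_raw),
    fences = list(lo = sc$fence_lo, hi = sc$fence_hi))
  expect_equal(sum(tab2$split == "excluded"), 0)
})

test_that("split counts, determinism and partition hold", {
  set.seed(4)
  raw <- data.frame(cell_id = rep(paste0("c", 1:10), 10),
                    drug_id = rep(paste0("d", 1:10), each = 10),
                    ic50 = exp(rnorm(100)))
  tab <- preprocess_responses(raw, iqr_factor = 10) # keep all 100
  s1 <- make_split(tab, seed = 7)
  expect_equal(as.vector(table(s1$split)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  # identical seed => identical labels
  s2 <- make_split(tab, seed = 7)
  expect_identical(s1$split, s2$split)
  # different seed => different assignment (overwhelmingly)
  s3 <- make_split(tab, seed = 8)
  expect_false(identical(s1$split, s3$split))
  # every non-excluded row in exactly one split
  expect_true(all(s1$split %in% c("train", "val", "test")))
})

test_that("per-drug stratified proportions deviate by at most one row", {
  set.seed(5)
  raw <- data.frame(cell_id = rep(paste0("c", 1:20), 12),
                    drug_id = rep(paste0("d", 1:12), each = 20),
                    ic50 = exp(rnorm(240)))
  tab <- make_split(preprocess_responses(raw, iqr_factor = 10), seed = 1)
  for (d in unique(tab$drug_id)) {
    sel <- tab$drug_id == d & tab$split != "excluded"
    n <- sum(sel)
    frac <- mean(tab$split[sel] == "train")
    expect_lte(abs(frac - 0.8), 1 / n + 1e-12)
  }
})

test_that("training subsample freezes validation and test sets", {
  tab <- fixture_bundle()$responses
  n_train <- sum(tab$split == "train")
  sub <- subsample_train(tab, 1 / 4, seed = 3)
  expect_equal(sum(sub$split == "train"), round(n_train / 4))
  expect_identical(which(sub$split == "val"), which(tab$split == "val"))
  expect_identical(which(sub$split == "test"), which(tab$split == "test"))
  expect_true(all(sub$exclude_reason[sub$split == "excluded" &
                                       !is.na(sub$exclude_reason)] %in%
                    c("iqr_outlier", "subsampled_out")))
  # the same semantics via make_split's subsample_fraction
  raw <- data.frame(cell_id = rep(paste0("c", 1:10), 10),
                    drug_id = rep(paste0("d", 1:10), each = 10),
                    ic50 = exp(rnorm(100)))
  s <- make_split(preprocess_responses(raw, iqr_factor = 10), seed = 2,
                  subsample_fraction = 1 / 4)
  expect_equal(sum(s$split == "train"), 20)
  expect_equal(sum(s$split == "val"), 10)
  expect_equal(sum(s$split == "test"), 10)
})

test_that("dataset bundles round-trip exactly and detect tampering", {
  b <- tiny_bundle()
  d <- withr::local_tempdir()
  write_dataset(b, d)
  b2 <- read_dataset(d)
  expect_equal(b2$omics$ge, b$omics$ge, tolerance = 1e-12)
  expect_equal(b2$omics$observed, b$omics$observed)
  expect_identical(b2$drugs$token_seqs, b$drugs$token_seqs)
  expect_equal(b2$responses$y, b$responses$y, tolerance = 1e-12)
  expect_equal(attr(b2$responses, "scaling")$y_min,
               attr(b$responses, "scaling")$y_min, tolerance = 1e-12)

  # tampering with a file breaks the checksum
  rl <- readLines(file.path(d, "responses.csv"))
  rl[2] <- sub(",", ",x", rl[2])
  writeLines(rl, file.path(d, "responses.csv"))
  expect_error(read_dataset(d), "checksum mismatch")

  # version mismatch is a hard error
  d2 <- withr::local_tempdir()
  write_dataset(b, d2)
  mf <- jsonlite::read_json(file.path(d2, "manifest.json"))
  mf$version <- "999"
  jsonlite::write_json(mf, file.path(d2, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_dataset(d2), "version mismatch")
})

test_that("an empty response table survives the round-trip", {
  b <- tiny_bundle()
  b$responses <- b$responses[0, , drop = FALSE]
  class(b$responses) <- c("mkdr_responses", "data.frame")
  d <- withr::local_tempdir()
  write_dataset(b, d)
  expect_equal(nrow(read_dataset(d)$responses), 0)
})
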