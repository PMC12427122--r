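# SMILES tokenisation, scaled dot-product attention, and the omics/drug
# encoders.

test_that("atom-level tokenisation follows the published token pattern", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  # two-letter halogen stays whole; ring digits are single tokens
  toks <- tokenize_smiles("c1ccccc1Cl")
  expect_identical(toks, c("c", "1", "c", "c", "c", "c", "c", "1", "Cl"))
  expect_identical(tokenize_smiles("CC(=O)[O-]"),
                   c("C", "C", "(", "=", "O", ")", "[O-]"))
  expect_identical(tokenize_smiles("C%12CC%12"),
                   c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize_smiles("BrC(Br)c1ccc(cc1)[nH]"),
                   c("Br", "C", "(", "Br", ")", "c", "1", "c", "c", "c",
                     "(", "c", "c", "1", ")", "[nH]"))
})

test_that("unbalanced brackets are rejected with a position", {
  expect_error(tokenize_smiles("CC[O-"), "unbalanced '\\[' at position 3")
  expect_error(tokenize_smiles("CCO]C"), "unbalanced '\\]' at position 4")
  expect_error(tokenize_smiles(""), "nonempty")
})

test_that("vocabulary reserves PAD=0/UNK=1 and maps unknown tokens to UNK", {
  v <- build_vocab(c("CCO", "c1ccccc1"))
  expect_identical(unname(v[".PAD"]), 0L)
  expect_identical(unname(v[".UNK"]), 1L)
  expect_true(all(v >= 0 & v < length(v)))
  # "N" was never seen: maps to UNK
  ids <- tokenize_smiles("CNO", vocab = v)
  expect_identical(ids[2], 1L)
  # padding and truncation to max_len
  ids_p <- tokenize_smiles("CCO", vocab = v, max_len = 6)
  expect_identical(ids_p[4:6], c(0L, 0L, 0L))
  expect_length(tokenize_smiles("c1ccccc1", vocab = v, max_len = 4), 4)
})

test_that("drug_library enforces its invariants", {
  dl <- drug_library(c("a", "b"), c("CCO", "CC(C)=O"))
  expect_length(dl$token_seqs, 2)
  expect_true(all(unlist(dl$token_seqs) < length(dl$vocab)))
  expect_error(drug_library(c("a", "a"), c("C", "C")), "duplicate drug ids")
})

test_that("attention rows are convex weights and match hand-computed values", {
  set.seed(1)
  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(20), 5, 4)
  V <- matrix(rnorm(10), 5, 2)
  a <- attention(Q, K, V)
  expect_true(all(a$weights >= 0))
  expect_equal(rowSums(a$weights), rep(1, 3), tolerance = 1e-6)

  # two keys with equal scores share the weight equally
  a2 <- attention(matrix(c(1, 0), 1), rbind(c(1, 1), c(1, 1)) / 2,
                  rbind(c(2, 0), c(0, 2)))
  expect_equal(drop(a2$weights), c(0.5, 0.5))

  # d = 1, Q = 1, K = (1, -1), V = (1, 0): output = softmax(c(1,-1)) . V
  a3 <- attention(matrix(1), matrix(c(1, -1), 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(drop(a3$out), exp(1) / (exp(1) + exp(-1)), tolerance = 1e-7)
  expect_equal(drop(a3$out), 0.8808, tolerance = 1e-4)

  # a single key/value row is returned unchanged for any query
  a4 <- attention(matrix(rnorm(4), 1), matrix(c(1, 2, 3, 4), 1),
                  matrix(c(9, 7), 1))
  expect_equal(drop(a4$out), c(9, 7))
  expect_error(attention(Q, K, V, d = 0), "positive")
  expect_error(attention(matrix(1, 1, 3), K, V), "widths differ")
})

test_that("modality encoding is deterministic and shape-checked", {
  m <- fixture_teacher()
  x <- fixture_teacher()$dims$n_ge
  b <- tiny_bundle()
  row <- b$omics$ge[1, ]
  e1 <- encode_modality(m, row, "ge")
  e2 <- encode_modality(m, row, "ge")
  expect_identical(e1$tokens, e2$tokens)
  expect_equal(dim(e1$tokens), c(m$cfg$n_tokens, m$cfg$d_model))
  expect_equal(e1$pooled, colMeans(e1$tokens))
  expect_true(all(is.finite(e1$tokens)))
  expect_error(encode_modality(m, row[-1], "ge"), "expected")
})

test_that("a single-token encoder degenerates to an MLP on the whole vector", {
  b <- tiny_bundle()
  m1 <- mkdr_model(ncol(b$omics$ge), ncol(b$omics$cnv), ncol(b$omics$mu),
                   length(b$drugs$vocab),
                   cfg = encoder_config(d_model = 8, n_heads = 1, n_layers = 1,
                                        n_tokens = 1, head_hidden = 8),
                   seed = 3)
  e <- encode_modality(m1, b$omics$ge[2, ], "ge")
  expect_equal(nrow(e$tokens), 1)
  # attention over one token is the identity on V: the block output equals
  # input + Wo(V(input)) + FFN(...); verify via the exported primitive
  one <- matrix(rnorm(8), 1)
  expect_equal(attention(one, one, one)$out, one)
})

test_that("drug embeddings ignore trailing PAD and are direction-sensitive", {
  m <- fixture_teacher()
  b <- tiny_bundle()
  toks <- b$drugs$token_seqs[[1]]
  toks <- toks[toks != 0]
  e <- encode_drug(m, toks)
  expect_length(e, m$cfg$d_model)
  expect_equal(encode_drug(m, c(toks, 0L, 0L, 0L)), e, tolerance = 1e-12)
  # reversing the sequence changes the embedding (bi-directional recurrence
  # is order-sensitive)
  expect_gt(max(abs(encode_drug(m, rev(toks)) - e)), 1e-6)
  expect_error(encode_drug(m, c(0L, 0L)), "all-PAD")
  expect_error(encode_drug(m, c(1L, 9999L)), "outside vocabulary")
})

test_that("mean and last pooling agree on single-token sequences", {
  b <- tiny_bundle()
  mk <- function(pool) {
    mkdr_model(ncol(b$omics$ge), ncol(b$omics$cnv), ncol(b$omics$mu),
               length(b$drugs$vocab),
               cfg = encoder_config(d_model = 8, n_heads = 2, n_layers = 1,
                                    n_tokens = 4, pool = pool, head_hidden = 8),
               seed = 7)
  }
  e_mean <- encode_drug(mk("mean"), 3L)
  e_last <- encode_drug(mk("last"), 3L)
  expect_equal(e_mean, e_last, tolerance = 1e-12)
})

test_that("gradient flows to every omics feature and drug position", {
  m <- fixture_teacher()
  b <- tiny_bundle()
  resp <- b$responses[b$responses$split == "train", ][1:6, ]
  inputs <- mkdr:::.pair_inputs(m, b, match(paste(resp$cell_id, resp$drug_id),
                                            paste(b$responses$cell_id, b$responses$drug_id)))
  tape <- mkdr:::tp_new()
  pn <- mkdr:::tp_params(tape, m$params)
  leaves <- list(ge = mkdr:::tp_leaf(tape, inputs$ge, requires_grad = TRUE),
                 cnv = mkdr:::tp_leaf(tape, inputs$cnv, requires_grad = TRUE),
                 mu = mkdr:::tp_leaf(tape, inputs$mu, requires_grad = TRUE))
  for (l in leaves) l$keep_grad <- TRUE
  fw <- mkdr:::.mkdr_forward(tape, pn, m, inputs, leaves = leaves)
  mkdr:::tp_backward(tape, mkdr:::tp_sum(tape, fw$pred))
  for (nm in names(leaves)) {
    g <- leaves[[nm]]$grad
    expect_true(all(colSums(abs(g)) > 0), info = nm)
  }
  # every non-PAD token position contributes: embedding-table rows used by
  # the batch receive gradient
  gE <- mkdr:::tp_grads(pn)$drug$E
  used <- sort(unique(as.vector(inputs$token_mat))) + 1L
  used <- used[used > 1] # PAD row excluded
  expect_true(all(rowSums(abs(gE))[used] > 0))
})
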