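# Distillation loss algebra, teacher/student training contracts, ablation
# grid bookkeeping.

test_that("the distillation loss reduces exactly as the equation dictates", {
  # alpha = 1: teacher ignored for any temperature
  for (T_ in c(0.5, 1, 4)) {
    l <- kd_loss(student_pred = 0.3, teacher_pred = 0.9, target = 0.1,
                 alpha = 1, temperature = T_)
    expect_identical(l$total, l$task)
    expect_equal(l$task, (0.3 - 0.1)^2)
  }
  # identical teacher and student: KL component is zero
  l0 <- kd_loss(0.4, 0.4, 0.2, alpha = 0.5, temperature = 1)
  expect_equal(l0$kl, 0)
  expect_equal(l0$total, 0.5 * l0$task)
  # alpha = 0.5, T = 1, teacher-student gap 2, student error 1:
  # total = 0.5 * 1 + 0.5 * (2^2 / 2) = 1.5
  l1 <- kd_loss(student_pred = 1, teacher_pred = 3, target = 2,
                alpha = 0.5, temperature = 1)
  expect_equal(l1$total, 1.5)
  expect_error(kd_loss(1, 1, 1, temperature = 0), "positive")
  expect_error(kd_loss(1, 1, 1, alpha = 2), "alpha")
})

test_that("the Gaussian divergence is symmetric in the gap and scales as 1/T^2", {
  set.seed(6)
  for (i in 1:20) {
    mt <- rnorm(1); ms <- rnorm(1); T_ <- runif(1, 0.2, 5)
    a <- kd_loss(ms, mt, 0, alpha = 0, temperature = T_)
    b <- kd_loss(mt, ms, 0, alpha = 0, temperature = T_)
    expect_equal(a$kl, b$kl)
    expect_equal(a$kl, (mt - ms)^2 / (2 * T_^2))
    expect_equal(kd_loss(ms, mt, 0, alpha = 0, temperature = 2 * T_)$kl,
                 a$kl / 4)
  }
})

test_that("teacher training needs complete cells and is seed-reproducible", {
  b <- tiny_bundle()
  b_all_missing <- b
  b_all_missing$omics$observed[, "mu"] <- FALSE
  expect_error(train_teacher(b_all_missing, cfg = light_cfg(), epochs = 2),
               "no fully observed")
  t1 <- train_teacher(b, cfg = light_cfg(), epochs = 8, seed = 4)
  t2 <- train_teacher(b, cfg = light_cfg(), epochs = 8, seed = 4)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
})

test_that("variant semantics: NK trains without a teacher, NM needs no completer", {
  b <- tiny_bundle()
  comp <- fixture_completer()
  nk <- train_student(b, teacher = NULL, completer = comp,
                      kd = kd_config(variant = "nk"), cfg = light_cfg(),
                      epochs = 5, seed = 3)
  expect_equal(nk$kd$alpha, 1)
  nm <- train_student(b, teacher = fixture_teacher(), completer = NULL,
                      kd = kd_config(variant = "nm"), cfg = light_cfg(),
                      epochs = 5, seed = 3)
  expect_true(nm$trained)
  expect_error(train_student(b, kd = kd_config(variant = "full"),
                             cfg = light_cfg(), epochs = 2),
               "requires a trained completer")
  expect_error(train_student(b, completer = comp, kd = kd_config(alpha = 0.5),
                             cfg = light_cfg(), epochs = 2),
               "requires a teacher")
})

test_that("alpha = 1 training is identical to training without a teacher", {
  b <- tiny_bundle()
  comp <- fixture_completer()
  with_teacher <- train_student(b, teacher = fixture_teacher(), completer = comp,
                                kd = kd_config(alpha = 1, temperature = 3),
                                cfg = light_cfg(), epochs = 6, seed = 5)
  without <- train_student(b, teacher = NULL, completer = comp,
                           kd = kd_config(variant = "nk"),
                           cfg = light_cfg(), epochs = 6, seed = 5)
  expect_identical(with_teacher$params, without$params)
})

test_that("teacher parameters never change during student training", {
  b <- tiny_bundle()
  te <- fixture_teacher()
  before <- te$params
  invisible(train_student(b, teacher = te, completer = fixture_completer(),
                          kd = kd_config(alpha = 0.5), cfg = light_cfg(),
                          epochs = 5, seed = 8))
  expect_identical(te$params, before)
})

test_that("binned-softmax divergence is an available alternative", {
  b <- tiny_bundle()
  st <- train_student(b, teacher = fixture_teacher(),
                      completer = fixture_completer(),
                      kd = kd_config(alpha = 0.5, kl_mode = "binned", n_bins = 10),
                      cfg = light_cfg(), epochs = 4, seed = 2)
  expect_true(st$trained)
  expect_true(all(is.finite(st$history$train_loss)))
})

test_that("feature compression keeps the top-variance fraction", {
  b <- fixture_bundle()
  cb <- compress_features(b, 0.2)
  expect_equal(ncol(cb$omics$ge), ceiling(0.2 * ncol(b$omics$ge)))
  expect_equal(ncol(cb$omics$ge), 40) # 200 GE features at 20%
  expect_equal(ncol(cb$omics$cnv), ceiling(0.2 * ncol(b$omics$cnv)))
  # kept features have the highest training-cell variance
  tr_cells <- unique(b$responses$cell_id[b$responses$split == "train"])
  v <- apply(b$omics$ge[match(tr_cells, b$omics$sample_ids), ], 2, var)
  expect_setequal(colnames(cb$omics$ge),
                  names(sort(v, decreasing = TRUE))[1:40])
})

test_that("the ablation grid emits one row per cell, seed and metric", {
  b <- tiny_bundle()
  tab <- run_ablation_suite(b, variants = c("nk", "nkm"), compressions = 1,
                            subsamples = c(1, 1 / 4), seeds = 1:2,
                            cfg = light_cfg(),
                            vae_cfg = vae_config(epochs = 30), epochs = 4)
  expect_equal(nrow(tab), 2 * 2 * 2 * 6)
  expect_setequal(unique(tab$metric), c("MSE", "RMSE", "MAE", "R2", "PCC", "SCC"))
  expect_true(all(tab$status == "ok"))
  # the test split is untouched by subsampling: per-variant test n equal
  expect_equal(length(unique(tab$value[tab$metric == "MSE"])), 8)
})
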