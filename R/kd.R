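# Teacher training, alpha-weighted knowledge distillation for the student,
# ablation variants and robustness sweeps.
#
# Predictions are scalar regressions; the distillation divergence treats the
# teacher and student predictions as Gaussians with common variance T^2, so
# KL(P_t || P_s) = (mu_t - mu_s)^2 / (2 T^2) and the temperature is a genuine
# softening knob. A binned-softmax alternative (discretise [0, 1], softmax
# logits at temperature T, standard KD divergence) is available behind
# `kl_mode = "binned"` for sensitivity analysis.

#' Knowledge distillation configuration
#'
#' @param alpha task-loss weight in `[0, 1]`; the distillation term gets
#'   `1 - alpha`. `alpha = 1` ignores the teacher entirely.
#' @param temperature softening scale T > 0.
#' @param variant `"full"` (completion + distillation), `"nk"` (completion,
#'   no distillation), `"nm"` (distillation, mean-fill instead of
#'   completion), `"nkm"` (neither).
#' @param kl_mode `"gaussian"` (closed form) or `"binned"` (discretised
#'   softmax divergence).
#' @param n_bins bins for `kl_mode = "binned"`.
#' @param fill_mode `"mean"` or `"zero"` fill for the no-completion variants.
#' @return list of class `mkdr_kd_config`.
#' @export
kd_config <- function(alpha = 0.5, temperature = 1,
                      variant = c("full", "nk", "nm", "nkm"),
                      kl_mode = c("gaussian", "binned"), n_bins = 20,
                      fill_mode = c("mean", "zero")) {
  variant <- match.arg(variant)
  kl_mode <- match.arg(kl_mode)
  fill_mode <- match.arg(fill_mode)
  stopifnot(alpha >= 0, alpha <= 1, temperature > 0)
  structure(list(alpha = alpha, temperature = temperature, variant = variant,
                 kl_mode = kl_mode, n_bins = n_bins, fill_mode = fill_mode),
            class = "mkdr_kd_config")
}

#' Distillation loss for scalar response prediction
#'
#' `alpha * L_task + (1 - alpha) * KL(P_teacher || P_student)` with
#' `L_task = (student - target)^2` and, under the Gaussian realisation,
#' `KL = (teacher - student)^2 / (2 T^2)`. All inputs may be vectors; the
#' components are averaged.
#'
#' @param student_pred,teacher_pred,target numeric vectors.
#' @param alpha task weight in `[0, 1]`.
#' @param temperature softening scale T > 0.
#' @return list with `total`, `task`, `kl`.
#' @examples
#' kd_loss(1, 3, 2, alpha = 0.5, temperature = 1)  # 0.5*1 + 0.5*2 = 1.5
#' @export
kd_loss <- function(student_pred, teacher_pred, target, alpha = 0.5,
                    temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  task <- mean((student_pred - target)^2)
  kl <- mean((teacher_pred - student_pred)^2) / (2 * temperature^2)
  list(total = alpha * task + (1 - alpha) * kl, task = task, kl = kl)
}

# tape version of the KD objective; teacher predictions are plain numbers
# (detached from the gradient path by construction)
.kd_loss_nodes <- function(tape, pred, y, teacher_pred, kd) {
  task <- tp_mean(tape, tp_square(tape, tp_shift(tape, pred, -y)))
  if (kd$alpha == 1 || is.null(teacher_pred)) {
    return(list(total = task, task = task, kl = NULL))
  }
  if (kd$kl_mode == "gaussian") {
    kl <- tp_scale(tape,
                   tp_mean(tape, tp_square(tape, tp_shift(tape, pred, -teacher_pred))),
                   1 / (2 * kd$temperature^2))
  } else {
    kl <- .binned_kl_nodes(tape, pred, teacher_pred, kd$n_bins, kd$temperature)
  }
  total <- tp_add(tape, tp_scale(tape, task, kd$alpha), tp_scale(tape, kl, 1 - kd$alpha))
  list(total = total, task = task, kl = kl)
}

# discretised divergence: logits_b = -(c_b - mu)^2 / (2 w^2), softened at T
.binned_kl_nodes <- function(tape, pred, teacher_pred, n_bins, temperature) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w <- 1 / n_bins
  B <- length(pred$val)
  Cm <- matrix(centers, B, n_bins, byrow = TRUE)
  # student logits depend on pred; build (B x n_bins) via outer ops
  predm <- tp_reshape(tape, pred, c(B, 1L))
  ones <- matrix(1, 1, n_bins)
  mu_s <- tp_matmul(tape, predm, tp_leaf(tape, ones)) # B x n_bins broadcast
  diff_s <- tp_op(tape, (Cm - mu_s$val), list(mu_s), function(g, nd) list(-g))
  logit_s <- tp_scale(tape, tp_square(tape, diff_s), -1 / (2 * w^2 * temperature))
  p_s <- tp_rowsoftmax(tape, logit_s)
  logit_t <- -(Cm - matrix(teacher_pred, B, n_bins))^2 / (2 * w^2 * temperature)
  p_t <- .rowsoftmax(logit_t)
  eps <- 1e-12
  log_ps <- tp_op(tape, log(p_s$val + eps), list(p_s),
                  function(g, nd) list(g / (nd$parents[[1]]$val + eps)))
  ce <- tp_dotc(tape, log_ps, -p_t / B)
  tp_shift(tape, ce, sum(p_t * log(p_t + eps)) / B)
}

# shared supervised training loop over response pairs
.fit_pairs <- function(model, bundle, train_rows, val_rows, inputs_train,
                       inputs_val, teacher_pred = NULL, kd = NULL,
                       epochs = 200, lr = 3e-3, patience = 25, seed = 1,
                       verbose = FALSE) {
  if (is.null(kd)) kd <- kd_config(alpha = 1)
  old <- .seed_swap(seed + 1L)
  on.exit(.seed_restore(old), add = TRUE)
  params <- model$params
  opt <- adam_new(params, lr = lr)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     task = numeric(0), val_mse = numeric(0))
  y <- inputs_train$y
  for (ep in seq_len(epochs)) {
    tape <- tp_new()
    pn <- tp_params(tape, params)
    fw <- .mkdr_forward(tape, pn, model, inputs_train, train = TRUE)
    loss <- .kd_loss_nodes(tape, fw$pred, y, teacher_pred, kd)
    tp_backward(tape, loss$total)
    params <- adam_step(opt, params, tp_grads(pn))
    # validation pass (eval mode, no gradient bookkeeping needed)
    tape_v <- tp_new()
    pn_v <- tp_params(tape_v, params)
    fw_v <- .mkdr_forward(tape_v, pn_v, model, inputs_val)
    val_mse <- mean((drop(fw_v$pred$val) - inputs_val$y)^2)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = loss$total$val,
                                   task = loss$task$val, val_mse = val_mse))
    if (val_mse < best$val - 1e-9) {
      best <- list(val = val_mse, params = params, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      if (verbose) message(sprintf("early stop at epoch %d (best %d)", ep, best$epoch))
      break
    }
    if (verbose && ep %% 20 == 0) {
      message(sprintf("epoch %d: loss %.5f val MSE %.5f", ep, loss$total$val, val_mse))
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Train the teacher model on complete-modality cells
#'
#' Fits the full network by mean squared error on the training rows whose
#' cell lines have all three modalities observed, with early stopping on
#' validation MSE.
#'
#' @param bundle dataset bundle with split labels assigned.
#' @param cfg [encoder_config()].
#' @param epochs,lr,patience optimiser settings.
#' @param seed seed (initialisation is reproducible from it).
#' @param residual keep the drug residual connection in fusion.
#' @param verbose progress messages.
#' @return fitted `mkdr_model` of class `mkdr_teacher`, with `history` and
#'   test `metrics` when a test split exists.
#' @export
train_teacher <- function(bundle, cfg = encoder_config(), epochs = 200,
                          lr = 3e-3, patience = 25, seed = 1, residual = TRUE,
                          verbose = FALSE) {
  resp <- bundle$responses
  complete_cells <- bundle$omics$sample_ids[rowSums(bundle$omics$observed) == 3L]
  train_rows <- which(resp$split == "train" & resp$cell_id %in% complete_cells)
  if (length(train_rows) == 0) stop("no fully observed training cells")
  val_rows <- which(resp$split == "val" & resp$cell_id %in% complete_cells)
  if (length(val_rows) == 0) val_rows <- train_rows
  model <- mkdr_model(ncol(bundle$omics$ge), ncol(bundle$omics$cnv),
                      ncol(bundle$omics$mu), length(bundle$drugs$vocab),
                      cfg = cfg, role = "teacher", residual = residual, seed = seed)
  inputs_train <- .pair_inputs(model, bundle, train_rows)
  inputs_val <- .pair_inputs(model, bundle, val_rows)
  model <- .fit_pairs(model, bundle, train_rows, val_rows, inputs_train,
                      inputs_val, epochs = epochs, lr = lr,
                      patience = patience, seed = seed, verbose = verbose)
  model$metrics <- .test_metrics(model, bundle, completer = NULL)
  model
}

#' Train the student model under missing modalities
#'
#' The student always consumes gene expression; CNV/MU inputs come from the
#' VAE completer (variants `full`, `nk`) or a training-set mean fill
#' (variants `nm`, `nkm`). Distillation targets are the teacher's
#' predictions on its own view of each training pair — complete inputs where
#' available, completed otherwise. With `alpha = 1` (variants `nk`, `nkm`)
#' the teacher is ignored and need not be supplied.
#'
#' @param bundle dataset bundle with split labels.
#' @param teacher fitted teacher (required unless `kd$variant` forces
#'   `alpha = 1`).
#' @param completer fitted [fit_vae()] completer (required for variants
#'   `full`/`nk`).
#' @param kd [kd_config()].
#' @param cfg [encoder_config()]; defaults to the teacher's.
#' @param epochs,lr,patience,seed,residual,verbose as in [train_teacher()].
#' @return fitted `mkdr_model` of class `mkdr_student`.
#' @export
train_student <- function(bundle, teacher = NULL, completer = NULL,
                          kd = kd_config(), cfg = NULL, epochs = 200,
                          lr = 3e-3, patience = 25, seed = 1, residual = TRUE,
                          verbose = FALSE) {
  kd <- .apply_variant(kd)
  if (kd$variant %in% c("full", "nk") && is.null(completer)) {
    stop("variant ", kd$variant, " requires a trained completer")
  }
  if (kd$alpha < 1 && is.null(teacher)) stop("distillation requires a teacher")
  if (is.null(cfg)) cfg <- if (!is.null(teacher)) teacher$cfg else encoder_config()
  resp <- bundle$responses
  train_rows <- which(resp$split == "train" & resp$cell_id %in%
                        bundle$omics$sample_ids[bundle$omics$observed[, "ge"]])
  if (length(train_rows) == 0) stop("no training rows with observed gene expression")
  val_rows <- which(resp$split == "val")
  if (length(val_rows) == 0) val_rows <- train_rows
  model <- mkdr_model(ncol(bundle$omics$ge), ncol(bundle$omics$cnv),
                      ncol(bundle$omics$mu), length(bundle$drugs$vocab),
                      cfg = cfg, role = "student", residual = residual, seed = seed)
  fill <- .variant_fill(kd, bundle)
  use_comp <- if (kd$variant %in% c("full", "nk")) completer else NULL
  inputs_train <- .pair_inputs(model, bundle, train_rows, completer = use_comp, fill = fill)
  inputs_val <- .pair_inputs(model, bundle, val_rows, completer = use_comp, fill = fill)
  teacher_pred <- NULL
  if (kd$alpha < 1) {
    teacher_pred <- .teacher_view_predictions(teacher, bundle, train_rows, completer, fill)
  }
  model <- .fit_pairs(model, bundle, train_rows, val_rows, inputs_train,
                      inputs_val, teacher_pred = teacher_pred, kd = kd,
                      epochs = epochs, lr = lr, patience = patience,
                      seed = seed, verbose = verbose)
  model$kd <- kd
  model$metrics <- .test_metrics(model, bundle, completer = use_comp, fill = fill)
  model
}

.apply_variant <- function(kd) {
  if (kd$variant %in% c("nk", "nkm")) kd$alpha <- 1
  kd
}

.variant_fill <- function(kd, bundle) {
  if (!(kd$variant %in% c("nm", "nkm"))) return(NULL)
  if (kd$fill_mode == "zero") {
    list(cnv = rep(0, ncol(bundle$omics$cnv)), mu = rep(0, ncol(bundle$omics$mu)))
  } else {
    tr_cells <- unique(bundle$responses$cell_id[bundle$responses$split == "train"])
    .mean_fill(bundle$omics, cells = intersect(tr_cells, bundle$omics$sample_ids))
  }
}

# teacher predictions on its own (complete-where-available) view
.teacher_view_predictions <- function(teacher, bundle, rows, completer, fill) {
  pairs <- bundle$responses[rows, c("cell_id", "drug_id")]
  .predict_pairs(teacher, bundle, pairs, completer = completer, fill = fill)
}

.test_metrics <- function(model, bundle, completer = NULL, fill = NULL) {
  rows <- which(bundle$responses$split == "test")
  if (model$role == "teacher" && is.null(completer) && is.null(fill)) {
    complete_cells <- bundle$omics$sample_ids[rowSums(bundle$omics$observed) == 3L]
    rows <- rows[bundle$responses$cell_id[rows] %in% complete_cells]
  }
  if (length(rows) < 2) return(NULL)
  pred <- .predict_pairs(model, bundle,
                         bundle$responses[rows, c("cell_id", "drug_id")],
                         completer, fill)
  compute_metrics(bundle$responses$y[rows], pred)
}

#' Evaluate a fitted model on a split
#'
#' @param model fitted `mkdr_model`.
#' @param bundle dataset bundle.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param completer,fill forwarded to [predict.mkdr_model()].
#' @param per_drug also return the per-drug table.
#' @return `mkdr_metrics`, with a `per_drug` attribute when requested.
#' @export
evaluate_model <- function(model, bundle, split = "test", completer = NULL,
                           fill = NULL, per_drug = FALSE) {
  rows <- which(bundle$responses$split == split)
  if (length(rows) < 2) stop("split ", split, " has fewer than 2 rows")
  pairs <- bundle$responses[rows, c("cell_id", "drug_id")]
  pred <- .predict_pairs(model, bundle, pairs, completer, fill)
  m <- compute_metrics(bundle$responses$y[rows], pred)
  if (per_drug) {
    attr(m, "per_drug") <- per_drug_table(bundle$responses$y[rows], pred, pairs$drug_id)
  }
  m
}

# ---- feature compression and subsampling helpers ---------------------------

#' Compress omics feature dimension by training-set variance
#'
#' Keeps the top `ceiling(fraction * n)` features of each omics modality,
#' ranked by variance over the training cells, and returns a bundle with the
#' reduced matrices.
#'
#' @param bundle dataset bundle.
#' @param fraction fraction of features kept, in (0, 1].
#' @return the compressed bundle.
#' @export
compress_features <- function(bundle, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(bundle)
  tr_cells <- unique(bundle$responses$cell_id[bundle$responses$split == "train"])
  om <- bundle$omics
  idx <- match(intersect(tr_cells, om$sample_ids), om$sample_ids)
  keep_of <- function(mat, modality) {
    use <- idx[om$observed[idx, modality]]
    v <- apply(mat[use, , drop = FALSE], 2, stats::var)
    n_keep <- ceiling(fraction * ncol(mat))
    sort(order(v, decreasing = TRUE)[seq_len(n_keep)])
  }
  kg <- keep_of(om$ge, "ge"); kc <- keep_of(om$cnv, "cnv"); km <- keep_of(om$mu, "mu")
  bundle$omics <- omics_dataset(om$ge[, kg, drop = FALSE],
                                om$cnv[, kc, drop = FALSE],
                                om$mu[, km, drop = FALSE],
                                observed = om$observed)
  bundle
}

#' Subsample the training split
#'
#' Relabels a random fraction of training rows as excluded
#' (`"subsampled_out"`), leaving validation and test untouched.
#'
#' @param responses `mkdr_responses` with split labels.
#' @param fraction fraction of training rows kept.
#' @param seed integer seed.
#' @return the relabelled table.
#' @export
subsample_train <- function(responses, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(responses)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old), add = TRUE)
  tr <- which(responses$split == "train")
  keep <- sort(sample(tr, round(length(tr) * fraction)))
  drop <- setdiff(tr, keep)
  responses$split[drop] <- "excluded"
  responses$exclude_reason[drop] <- "subsampled_out"
  responses
}

#' Run the ablation and robustness grid
#'
#' For every combination of variant, compression fraction, training
#' subsample and seed: fits the required components (VAE completer, teacher,
#' student), evaluates the six metrics on the fixed test split, and returns
#' one tidy row per (variant, compression, subsample, seed, metric). A
#' failing cell is recorded (`status = "error"`) and the suite continues.
#'
#' @param bundle dataset bundle with split labels.
#' @param variants character subset of `c("full", "nk", "nm", "nkm")`.
#' @param compressions numeric fractions in (0, 1].
#' @param subsamples numeric fractions in (0, 1].
#' @param seeds integer vector.
#' @param cfg [encoder_config()] used for teacher and student.
#' @param vae_cfg [vae_config()] for the completer.
#' @param epochs,lr,patience training settings.
#' @param verbose progress messages.
#' @return data.frame with columns variant, compression, subsample, seed,
#'   metric, value, status.
#' @export
run_ablation_suite <- function(bundle, variants = c("full", "nkm"),
                               compressions = 1, subsamples = 1,
                               seeds = 1:3, cfg = encoder_config(),
                               vae_cfg = vae_config(), epochs = 120,
                               lr = 3e-3, patience = 20, verbose = FALSE) {
  stopifnot(length(variants) > 0, length(compressions) > 0,
            length(subsamples) > 0, length(seeds) > 0)
  out <- list()
  metric_names <- c("MSE", "RMSE", "MAE", "R2", "PCC", "SCC")
  for (f in compressions) {
    b_f <- compress_features(bundle, f)
    for (ss in subsamples) {
      for (sd in seeds) {
        b <- b_f
        b$responses <- subsample_train(b_f$responses, ss, seed = sd)
        comp_cache <- NULL; teach_cache <- NULL
        for (v in variants) {
          res <- tryCatch({
            kd <- kd_config(variant = v)
            kd <- .apply_variant(kd)
            needs_comp <- v %in% c("full", "nk")
            needs_teacher <- kd$alpha < 1
            if (needs_comp && is.null(comp_cache)) {
              vc <- vae_cfg; vc$seed <- sd
              comp_cache <- fit_vae(b$omics, vc)
            }
            if (needs_teacher && is.null(teach_cache)) {
              teach_cache <- train_teacher(b, cfg = cfg, epochs = epochs,
                                           lr = lr, patience = patience, seed = sd)
            }
            st <- train_student(b,
                                teacher = if (needs_teacher) teach_cache else NULL,
                                completer = if (needs_comp) comp_cache else NULL,
                                kd = kd_config(variant = v), cfg = cfg,
                                epochs = epochs, lr = lr, patience = patience,
                                seed = sd)
            m <- st$metrics
            data.frame(variant = v, compression = f, subsample = ss, seed = sd,
                       metric = metric_names,
                       value = unlist(m[metric_names], use.names = FALSE),
                       status = "ok", stringsAsFactors = FALSE)
          }, error = function(e) {
            data.frame(variant = v, compression = f, subsample = ss, seed = sd,
                       metric = metric_names, value = NA_real_,
                       status = paste("error:", conditionMessage(e)),
                       stringsAsFactors = FALSE)
          })
          out[[length(out) + 1]] <- res
          if (verbose) message(sprintf("ablation: variant=%s f=%.2f ss=%.3f seed=%d done", v, f, ss, sd))
        }
      }
    }
  }
  do.call(rbind, out)
}
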