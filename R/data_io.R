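# Omics matrices, response preprocessing, stratified splits and dataset
# bundles.
#
# Omics files are delimited matrices (samples x features) with a header row
# of feature names and the sample id in the first column. Responses are
# (cell_id, drug_id, ic50) triples. A dataset bundle is a directory of these
# files plus a JSON manifest carrying version, checksums and the response
# scaling constants.

.BUNDLE_VERSION <- "1"

#' Construct an aligned multi-omics dataset
#'
#' Holds gene expression (GE, continuous), copy number variation (CNV,
#' continuous) and mutation (MU, binary) matrices over the same samples, with
#' an explicit per-sample, per-modality observed mask. Unobserved rows carry
#' `NA` values and are flagged in the mask — never silently zero-filled.
#'
#' @param ge,cnv,mu numeric matrices (samples x features) with rownames =
#'   sample ids and colnames = feature names. A modality absent for all
#'   samples may be a 0-column matrix.
#' @param observed logical matrix (samples x 3, columns ge/cnv/mu). Default:
#'   rows with no NA are observed.
#' @return object of class `mkdr_omics`.
#' @export
omics_dataset <- function(ge, cnv, mu, observed = NULL) {
  ids <- rownames(ge)
  if (is.null(ids)) stop("ge must have sample ids as rownames")
  if (anyDuplicated(ids)) stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  mats <- list(ge = ge, cnv = cnv, mu = mu)
  for (m in names(mats)) {
    x <- mats[[m]]
    if (!is.matrix(x)) stop(m, " must be a matrix")
    if (nrow(x) != length(ids)) stop(m, " row count differs from ge")
    if (!identical(rownames(x), ids)) stop(m, " row order differs from ge")
    fn <- colnames(x)
    if (ncol(x) > 0 && (is.null(fn) || anyDuplicated(fn))) {
      stop(m, " must have unique feature names as colnames")
    }
  }
  if (is.null(observed)) {
    observed <- vapply(mats, function(x) {
      if (ncol(x) == 0) rep(FALSE, length(ids)) else stats::complete.cases(x)
    }, logical(length(ids)))
    if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1, dimnames = list(NULL, names(mats)))
  }
  observed <- as.matrix(observed)
  rownames(observed) <- ids
  # observed rows must be clean; mutation entries must be 0/1
  for (m in names(mats)) {
    x <- mats[[m]][observed[, m], , drop = FALSE]
    if (anyNA(x)) stop("NA inside observed ", m, " rows")
  }
  muo <- mats$mu[observed[, "mu"], , drop = FALSE]
  if (length(muo) > 0) {
    bad <- which(!(muo %in% c(0, 1)))
    if (length(bad) > 0) {
      i <- arrayInd(bad[1], dim(muo))
      stop(sprintf("non-binary mutation value %g at sample %s, feature %s",
                   muo[bad[1]], rownames(muo)[i[1]], colnames(muo)[i[2]]))
    }
  }
  structure(list(sample_ids = ids, ge = ge, cnv = cnv, mu = mu,
                 feature_names = lapply(mats, colnames), observed = observed),
            class = "mkdr_omics")
}

#' @export
print.mkdr_omics <- function(x, ...) {
  cat(sprintf("Multi-omics dataset: %d samples; GE %d, CNV %d, MU %d features\n",
              length(x$sample_ids), ncol(x$ge), ncol(x$cnv), ncol(x$mu)))
  cat("observed samples per modality:",
      paste(sprintf("%s=%d", colnames(x$observed), colSums(x$observed)), collapse = ", "), "\n")
  invisible(x)
}

#' Load omics matrices from delimited files
#'
#' Reads per-modality matrices (header = feature names, first column = sample
#' id) and restricts to the intersection of sample ids across the provided
#' modalities. A modality whose path is `NULL` is marked unobserved for all
#' samples.
#'
#' @param paths named list with entries `ge`, `cnv`, `mu`; each a file path or
#'   `NULL`.
#' @param sep field separator (default `,`).
#' @return `mkdr_omics` object.
#' @export
load_omics <- function(paths, sep = ",") {
  stopifnot(is.list(paths))
  read_one <- function(p) {
    if (is.null(p)) return(NULL)
    df <- utils::read.table(p, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    # duplicate sample ids would have failed row.names; double-check
    as.matrix(df)
  }
  mats <- list(ge = read_one(paths$ge), cnv = read_one(paths$cnv), mu = read_one(paths$mu))
  present <- !vapply(mats, is.null, TRUE)
  if (!any(present)) stop("no modality files provided")
  ids <- Reduce(intersect, lapply(mats[present], rownames))
  if (length(ids) == 0) stop("no samples shared across provided modalities")
  out <- list()
  obs <- matrix(FALSE, length(ids), 3, dimnames = list(ids, c("ge", "cnv", "mu")))
  for (m in c("ge", "cnv", "mu")) {
    if (present[[m]]) {
      out[[m]] <- mats[[m]][ids, , drop = FALSE]
      obs[, m] <- stats::complete.cases(out[[m]])
    } else {
      out[[m]] <- matrix(numeric(0), length(ids), 0, dimnames = list(ids, NULL))
    }
  }
  omics_dataset(out$ge, out$cnv, out$mu, observed = obs)
}

#' Preprocess raw IC50 responses
#'
#' Log-transforms IC50 concentrations, excludes outliers by the IQR fence
#' rule (values outside `[Q1 - k*IQR, Q3 + k*IQR]` on the log scale, linear-
#' interpolation quantiles), and min-max scales the surviving log values to
#' `[0, 1]`. The fences and scaling constants are stored with the table so
#' the transform is frozen and invertible.
#'
#' @param raw data.frame with columns `cell_id`, `drug_id`, `ic50` (all
#'   `ic50 > 0`).
#' @param log_base base of the log transform (default natural log).
#' @param iqr_factor fence multiplier k (default 1.5).
#' @param per_drug_fences compute fences within each drug instead of
#'   globally (default FALSE).
#' @param fences optional frozen fences (named list with `lo`, `hi`) to apply
#'   instead of recomputing; used to re-apply a stored exclusion rule.
#' @return data.frame of class `mkdr_responses` with columns cell_id,
#'   drug_id, y_raw, y_log, y, split (`"unassigned"`/`"excluded"`),
#'   exclude_reason; scaling constants in `attr(, "scaling")`.
#' @export
preprocess_responses <- function(raw, log_base = exp(1), iqr_factor = 1.5,
                                 per_drug_fences = FALSE, fences = NULL) {
  stopifnot(all(c("cell_id", "drug_id", "ic50") %in% names(raw)))
  if (any(raw$ic50 <= 0) || anyNA(raw$ic50)) stop("nonpositive or missing IC50 values")
  if (anyDuplicated(raw[, c("cell_id", "drug_id")])) {
    stop("duplicate (cell_id, drug_id) pairs")
  }
  y_log <- log(raw$ic50) / log(log_base)
  fence_of <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    list(lo = q[1] - iqr_factor * iqr, hi = q[2] + iqr_factor * iqr, q1 = q[1], q3 = q[2])
  }
  if (!is.null(fences)) {
    keep <- y_log >= fences$lo & y_log <= fences$hi
    fl <- fences
  } else if (per_drug_fences) {
    keep <- rep(TRUE, length(y_log))
    for (d in unique(raw$drug_id)) {
      sel <- raw$drug_id == d
      f <- fence_of(y_log[sel])
      keep[sel] <- y_log[sel] >= f$lo & y_log[sel] <= f$hi
    }
    fl <- fence_of(y_log) # global fences stored for reference
  } else {
    fl <- fence_of(y_log)
    keep <- y_log >= fl$lo & y_log <= fl$hi
  }
  if (!any(keep)) stop("all rows excluded by the IQR rule")
  rng <- range(y_log[keep])
  if (diff(rng) == 0) stop("zero range: all kept log-IC50 values identical, cannot scale")
  y <- ifelse(keep, (y_log - rng[1]) / diff(rng), NA_real_)
  out <- data.frame(cell_id = as.character(raw$cell_id),
                    drug_id = as.character(raw$drug_id),
                    y_raw = raw$ic50, y_log = y_log, y = y,
                    split = ifelse(keep, "unassigned", "excluded"),
                    exclude_reason = ifelse(keep, NA_character_, "iqr_outlier"),
                    stringsAsFactors = FALSE)
  attr(out, "scaling") <- list(log_base = log_base, iqr_factor = iqr_factor,
                               fence_lo = fl$lo, fence_hi = fl$hi,
                               q1 = fl$q1, q3 = fl$q3,
                               y_min = rng[1], y_max = rng[2],
                               per_drug_fences = per_drug_fences)
  class(out) <- c("mkdr_responses", "data.frame")
  out
}

#' Invert the response transform
#'
#' Maps scaled responses on `[0, 1]` back to IC50 concentrations using the
#' scaling constants frozen by [preprocess_responses()].
#'
#' @param y numeric vector of scaled responses.
#' @param scaling the `attr(table, "scaling")` list.
#' @return IC50 concentrations.
#' @export
inverse_response <- function(y, scaling) {
  y_log <- y * (scaling$y_max - scaling$y_min) + scaling$y_min
  scaling$log_base^y_log
}

#' Assign train/validation/test split labels
#'
#' Randomly partitions non-excluded rows into train/val/test at the given
#' fractions. With `stratify_by = "drug"` each drug's rows are allocated by
#' largest remainder so per-drug proportions deviate from the global
#' fractions by at most one row; drugs with fewer rows than split bins fall
#' back to pooled assignment with a warning. `subsample_fraction < 1` keeps
#' that fraction of training rows and marks the rest excluded
#' (`"subsampled_out"`), leaving validation and test untouched.
#'
#' @param table `mkdr_responses` table (>= 10 non-excluded rows).
#' @param fractions named numeric (train, val, test) summing to 1.
#' @param stratify_by `"drug"`, `"cell"` or `"none"`.
#' @param seed integer seed; identical seeds give identical labels.
#' @param subsample_fraction fraction of training rows to keep.
#' @param rescale_on_train recompute the min-max scaling of `y` on the
#'   training rows only (default FALSE: scaling from preprocessing is kept so
#'   all responses stay in `[0, 1]`).
#' @return the table with `split` filled in.
#' @export
make_split <- function(table, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                       stratify_by = c("drug", "cell", "none"), seed = 1,
                       subsample_fraction = 1, rescale_on_train = FALSE) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  active <- which(table$split != "excluded")
  if (length(active) < 10) stop("need at least 10 non-excluded rows to split")
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old), add = TRUE)

  labels <- rep(NA_character_, length(active))
  key <- switch(stratify_by,
                drug = table$drug_id[active],
                cell = table$cell_id[active],
                none = rep("all", length(active)))
  pooled <- integer(0)
  for (g in unique(key)) {
    idx <- which(key == g)
    if (stratify_by != "none" && length(idx) < length(fractions)) {
      pooled <- c(pooled, idx)
      next
    }
    labels[idx] <- .allocate(length(idx), fractions)
  }
  if (length(pooled) > 0) {
    warning(sprintf("%d rows from groups smaller than the number of split bins assigned by pooled allocation",
                    length(pooled)))
    labels[pooled] <- .allocate(length(pooled), fractions)
  }
  table$split[active] <- labels

  if (subsample_fraction < 1) {
    tr <- which(table$split == "train")
    n_keep <- round(length(tr) * subsample_fraction)
    keep <- sort(sample(tr, n_keep))
    drop <- setdiff(tr, keep)
    table$split[drop] <- "excluded"
    table$exclude_reason[drop] <- "subsampled_out"
  }
  if (rescale_on_train) {
    tr <- table$split == "train"
    rng <- range(table$y_log[tr])
    if (diff(rng) == 0) stop("zero range on training rows")
    sc <- attr(table, "scaling")
    sc$y_min <- rng[1]; sc$y_max <- rng[2]
    keep <- table$split != "excluded" | table$exclude_reason %in% "subsampled_out"
    table$y[keep] <- (table$y_log[keep] - rng[1]) / diff(rng)
    attr(table, "scaling") <- sc
  }
  table
}

# largest-remainder allocation of n shuffled rows to the named fractions
.allocate <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(exact - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  sample(rep(names(fractions), times = base))
}

# swap in a temporary RNG state so callers' streams are untouched
.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- bundle serialization --------------------------------------------------

#' Write a dataset bundle to a directory
#'
#' Serializes omics matrices, the drug library, the response table (with
#' split labels and scaling constants) and optional simulation truth as
#' plain-text files plus a JSON manifest with version and MD5 checksums.
#'
#' @param bundle list with `omics` (`mkdr_omics`), `drugs` (`mkdr_druglib`),
#'   `responses` (`mkdr_responses`), optional `truth`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  om <- bundle$omics
  files <- character(0)
  wm <- function(mat, file) {
    df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
    files <<- c(files, file)
  }
  wm(om$ge, "omics_ge.csv"); wm(om$cnv, "omics_cnv.csv"); wm(om$mu, "omics_mu.csv")
  wm(om$observed * 1L, "observed.csv")
  utils::write.csv(data.frame(drug_id = bundle$drugs$drug_ids,
                              smiles = unname(bundle$drugs$smiles)),
                   file.path(path, "drugs.csv"), row.names = FALSE)
  files <- c(files, "drugs.csv")
  utils::write.csv(as.data.frame(bundle$responses), file.path(path, "responses.csv"),
                   row.names = FALSE)
  files <- c(files, "responses.csv")
  if (!is.null(bundle$truth)) {
    saveRDS(bundle$truth, file.path(path, "truth.rds"))
    files <- c(files, "truth.rds")
  }
  sums <- as.list(tools::md5sum(file.path(path, files)))
  names(sums) <- files
  manifest <- list(version = .BUNDLE_VERSION,
                   files = files,
                   checksums = sums,
                   scaling = attr(bundle$responses, "scaling"),
                   vocab = as.list(bundle$drugs$vocab),
                   max_len = bundle$drugs$max_len)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a dataset bundle
#'
#' Validates the manifest version and file checksums, then reconstructs the
#' bundle written by [write_dataset()]. A version mismatch or a tampered file
#' is a hard error.
#'
#' @param path bundle directory.
#' @return bundle list (`omics`, `drugs`, `responses`, optional `truth`).
#' @export
read_dataset <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"))
  if (!identical(as.character(mf$version), .BUNDLE_VERSION)) {
    stop(sprintf("bundle version mismatch: found %s, expected %s", mf$version, .BUNDLE_VERSION))
  }
  for (f in mf$files) {
    got <- unname(tools::md5sum(file.path(path, f)))
    if (!identical(got, mf$checksums[[f]])) stop("checksum mismatch for ", f)
  }
  rm_ <- function(file) {
    df <- utils::read.csv(file.path(path, file), check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  ge <- rm_("omics_ge.csv"); cnv <- rm_("omics_cnv.csv"); mu <- rm_("omics_mu.csv")
  obs <- rm_("observed.csv") > 0
  om <- omics_dataset(ge, cnv, mu, observed = obs)
  dr <- utils::read.csv(file.path(path, "drugs.csv"), stringsAsFactors = FALSE)
  vocab <- unlist(mf$vocab)
  storage.mode(vocab) <- "integer"
  drugs <- drug_library(dr$drug_id, dr$smiles, vocab = vocab,
                        max_len = if (is.null(mf$max_len)) NULL else mf$max_len)
  resp <- utils::read.csv(file.path(path, "responses.csv"), stringsAsFactors = FALSE,
                          colClasses = c(cell_id = "character", drug_id = "character"))
  attr(resp, "scaling") <- mf$scaling
  class(resp) <- c("mkdr_responses", "data.frame")
  truth <- if (file.exists(file.path(path, "truth.rds"))) readRDS(file.path(path, "truth.rds")) else NULL
  list(omics = om, drugs = drugs, responses = resp, truth = truth)
}
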