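#' Six-metric evaluation of predicted versus observed drug response
#'
#' Computes the standard regression bundle used for drug response prediction:
#' mean squared error (MSE), root mean squared error (RMSE), mean absolute
#' error (MAE), coefficient of determination (R2), Pearson correlation (PCC)
#' and Spearman correlation (SCC, average ranks for ties).
#'
#' When `y_true` has zero variance the correlation-type metrics (R2, PCC, SCC)
#' are undefined and returned as `NA` with `undefined = TRUE`; the error
#' metrics are still computed.
#'
#' @param y_true numeric vector of observed responses (length >= 2, finite).
#' @param y_pred numeric vector of predictions, same length.
#' @return an object of class `mkdr_metrics`: a named list with the six
#'   metrics, `n`, and an `undefined` flag.
#' @examples
#' m <- compute_metrics(c(0.1, 0.4, 0.8), c(0.2, 0.35, 0.75))
#' m$RMSE^2 - m$MSE  # exactly zero
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred must have equal length")
  if (length(y_true) < 2) stop("need at least 2 observations")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) stop("inputs must be finite")
  err <- y_pred - y_true
  mse <- mean(err^2)
  mae <- mean(abs(err))
  sstot <- sum((y_true - mean(y_true))^2)
  undefined <- sstot == 0 || stats::sd(y_pred) == 0
  if (sstot == 0) {
    r2 <- NA_real_; pcc <- NA_real_; scc <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / sstot
    if (stats::sd(y_pred) == 0) {
      pcc <- NA_real_; scc <- NA_real_
    } else {
      pcc <- stats::cor(y_true, y_pred, method = "pearson")
      scc <- stats::cor(y_true, y_pred, method = "spearman")
    }
  }
  structure(
    list(MSE = mse, RMSE = sqrt(mse), MAE = mae, R2 = r2, PCC = pcc, SCC = scc,
         n = length(y_true), undefined = undefined),
    class = "mkdr_metrics"
  )
}

#' @export
print.mkdr_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Drug response metrics (n = %d)\n", x$n))
  v <- unlist(x[c("MSE", "RMSE", "MAE", "R2", "PCC", "SCC")])
  print(round(v, digits))
  invisible(x)
}

#' Per-drug metric table
#'
#' Groups predictions by drug and reports the six-metric bundle for every
#' drug with at least `min_n` pairs, plus a pooled `overall` row. Drugs
#' below the threshold are listed in the `excluded` attribute with a reason.
#'
#' @param y_true,y_pred numeric vectors.
#' @param drug_id character/factor vector of the same length.
#' @param min_n minimum pairs per drug (default 3).
#' @return data.frame with columns drug_id, n, MSE, RMSE, MAE, R2, PCC, SCC;
#'   first row is `overall`.
#' @export
per_drug_table <- function(y_true, y_pred, drug_id, min_n = 3) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) == length(drug_id))
  drug_id <- as.character(drug_id)
  row_of <- function(id, yt, yp) {
    m <- compute_metrics(yt, yp)
    data.frame(drug_id = id, n = m$n, MSE = m$MSE, RMSE = m$RMSE, MAE = m$MAE,
               R2 = m$R2, PCC = m$PCC, SCC = m$SCC, stringsAsFactors = FALSE)
  }
  out <- row_of("overall", y_true, y_pred)
  excluded <- character(0)
  for (d in sort(unique(drug_id))) {
    sel <- drug_id == d
    if (sum(sel) < min_n) {
      excluded <- c(excluded, sprintf("%s: n = %d < %d", d, sum(sel), min_n))
      next
    }
    out <- rbind(out, row_of(d, y_true[sel], y_pred[sel]))
  }
  attr(out, "excluded") <- excluded
  out
}

# AUROC of scores against binary labels; NA when only one class is present.
# Direction is fixed (higher score = positive class).
.auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(r$auc)
}
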