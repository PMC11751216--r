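#' Classification metrics for a binary run
#'
#' Confusion counts (positive class = buy = 1), accuracy, precision, recall
#' (sensitivity), specificity, F1, and — when scores are supplied — the exact
#' empirical ROC curve (thresholds swept over all unique score values) with
#' trapezoidal AUC.
#'
#' @param y_true,y_pred binary vectors.
#' @param scores optional positive-class scores in `[0, 1]`.
#' @return An object of class `metrics_bundle`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  out <- list(confusion = matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                                 dimnames = list(true = c("no_buy", "buy"),
                                                 pred = c("no_buy", "buy"))),
              accuracy = acc, precision = prec, recall = rec,
              specificity = spec, f1 = f1,
              auc = NA_real_, roc = NULL, auc_defined = FALSE)
  if (!is.null(scores)) {
    if (length(scores) != length(y_true))
      stop("scores must match y_true in length")
    if (length(unique(y_true)) < 2) {
      out$auc_defined <- FALSE   # AUC undefined with one class; flagged NA
    } else {
      roc <- empirical_roc(y_true, scores)
      out$roc <- roc
      out$auc <- trapezoid_auc(roc$fpr, roc$tpr)
      out$auc_defined <- TRUE
    }
  }
  structure(out, class = "metrics_bundle")
}

empirical_roc <- function(y, s) {
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  P <- sum(y == 1); N <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(s >= t & y == 1) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & y == 0) / N, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

#' @export
print.metrics_bundle <- function(x, digits = 4, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat(sprintf(paste0("accuracy %.*f | precision %.*f | recall %.*f | ",
                     "specificity %.*f | F1 %.*f"),
              digits, x$accuracy, digits, x$precision, digits, x$recall,
              digits, x$specificity, digits, x$f1))
  if (x$auc_defined) cat(sprintf(" | AUC %.*f", digits, x$auc))
  cat("\n")
  invisible(x)
}

#' Plot the ROC curve of a metrics bundle
#'
#' @param x a [compute_metrics()] result computed with scores.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metrics_bundle <- function(x, ...) {
  if (is.null(x$roc)) stop("no ROC available; compute_metrics needs scores")
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, specificity = m$specificity, f1 = m$f1,
             auc = m$auc,
             tp = m$confusion["buy", "buy"], tn = m$confusion["no_buy", "no_buy"],
             fp = m$confusion["no_buy", "buy"], fn = m$confusion["buy", "no_buy"])
}

#' Build a run report from a cross-validation result
#'
#' Collects per-fold and aggregate metrics together with the configuration
#' and seeds, as a JSON-serializable list; identical runs produce
#' byte-identical JSON.
#'
#' @param cv a `neurochoice_cv` object (see [crossvalidate()]).
#' @param path optional JSON output file.
#' @return The report list, invisibly when `path` is given.
#' @export
report <- function(cv, path = NULL) {
  if (!inherits(cv, "neurochoice_cv")) stop("report() expects a neurochoice_cv")
  k <- length(cv$fold_metrics)
  missing <- which(vapply(cv$fold_metrics, is.null, logical(1)))
  if (length(missing))
    stop("missing results for fold(s): ", paste(missing, collapse = ", "))
  per_fold <- do.call(rbind, lapply(cv$fold_metrics, metrics_row))
  per_fold <- cbind(fold = seq_len(k), per_fold)
  agg <- colMeans(per_fold[, c("accuracy", "precision", "recall",
                               "specificity", "f1", "auc")])
  sds <- apply(per_fold[, c("accuracy", "precision", "recall",
                            "specificity", "f1", "auc")], 2, stats::sd)
  rep <- list(config = cv$config, seed = cv$seed, folds = k,
              fold_assignments = cv$fold_assign,
              per_fold = per_fold,
              mean = as.list(round(agg, 10)),
              sd = as.list(round(sds, 10)),
              pooled = metrics_row(cv$pooled))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
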