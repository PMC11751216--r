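#' Pair EEG and ET windows from the same trials
#'
#' Windows are paired by (subject, trial, window ordinal). Both modalities
#' use 1-s windows with the same overlap, so ordinals line up in time; when
#' one modality produced fewer windows for a trial, pairs are truncated to
#' the shorter count (with a warning), and trials present in only one
#' modality are dropped (with a warning).
#'
#' @param eeg_ws,et_ws `nc_windows` objects from [preprocess_eeg()] /
#'   [preprocess_et()].
#' @return A list of class `nc_aligned`: `eeg_idx`, `et_idx` (parallel index
#'   vectors into the two window sets), `labels`, `subjects`, `trial_key`.
#' @export
align_windows <- function(eeg_ws, et_ws) {
  ek <- paste(eeg_ws$info$subject, eeg_ws$info$trial, sep = "/")
  tk <- paste(et_ws$info$subject, et_ws$info$trial, sep = "/")
  common <- intersect(unique(ek), unique(tk))
  missing <- setdiff(union(unique(ek), unique(tk)), common)
  if (length(missing))
    warning("dropping trial(s) present in one modality only: ",
            paste(missing, collapse = ", "))
  eeg_idx <- integer(); et_idx <- integer()
  labels <- integer(); subjects <- character(); trial_key <- character()
  for (key in common) {
    ei <- which(ek == key); ti <- which(tk == key)
    ei <- ei[order(eeg_ws$info$ordinal[ei])]
    ti <- ti[order(et_ws$info$ordinal[ti])]
    m <- min(length(ei), length(ti))
    if (length(ei) != length(ti))
      warning("trial ", key, ": ", length(ei), " EEG vs ", length(ti),
              " ET windows; truncating to ", m, " pairs")
    if (m == 0) next
    eeg_idx <- c(eeg_idx, ei[seq_len(m)])
    et_idx <- c(et_idx, ti[seq_len(m)])
    labels <- c(labels, eeg_ws$info$label[ei[seq_len(m)]])
    subjects <- c(subjects, eeg_ws$info$subject[ei[seq_len(m)]])
    trial_key <- c(trial_key, rep(key, m))
  }
  structure(list(eeg_idx = eeg_idx, et_idx = et_idx, labels = labels,
                 subjects = subjects, trial_key = trial_key),
            class = "nc_aligned")
}

#' Fuse per-modality feature blocks into one matrix
#'
#' Column-wise concatenation in a fixed order (EEG-deep, ET-deep, EEG-hand,
#' ET-hand, as the mode and modality dictate) with a column provenance map.
#' In `deep_only` mode with flatten-level features the fused width is
#' 14,016 + 2,704 = 16,720.
#'
#' @param blocks named list of feature matrices with equal row counts; any of
#'   `eeg_deep`, `et_deep`, `eeg_hand`, `et_hand` may be present.
#' @param labels binary label vector, one per row.
#' @param subjects optional subject id per row.
#' @param mode `"full"`, `"deep_only"` or `"hand_only"`.
#' @param modality `"both"`, `"eeg"` or `"et"`.
#' @return An object of class `fused_features`: `X`, `y`, `subjects`,
#'   `provenance` (block name per column), `mode`, `modality`.
#' @export
fuse <- function(blocks, labels, subjects = NULL,
                 mode = c("full", "deep_only", "hand_only"),
                 modality = c("both", "eeg", "et")) {
  mode <- match.arg(mode)
  modality <- match.arg(modality)
  want <- c("eeg_deep", "et_deep", "eeg_hand", "et_hand")
  if (mode == "deep_only") want <- c("eeg_deep", "et_deep")
  if (mode == "hand_only") want <- c("eeg_hand", "et_hand")
  if (modality == "eeg") want <- grep("^eeg", want, value = TRUE)
  if (modality == "et") want <- grep("^et_", want, value = TRUE)
  use <- want[want %in% names(blocks)]
  if (!length(use)) stop("no feature blocks available for mode=", mode,
                         ", modality=", modality)
  nr <- vapply(blocks[use], nrow, integer(1))
  if (length(unique(nr)) != 1)
    stop("feature blocks have mismatched row counts: ",
         paste(nr, collapse = ", "))
  if (nr[1] != length(labels)) stop("labels do not match feature rows")
  X <- do.call(cbind, blocks[use])
  if (anyNA(X) || any(!is.finite(X))) stop("fused features contain NaN/Inf")
  provenance <- rep(use, vapply(blocks[use], ncol, integer(1)))
  structure(list(X = X, y = as.integer(labels), subjects = subjects,
                 provenance = provenance, mode = mode, modality = modality),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("<fused_features> %d windows x %d features (%s, %s): %s\n",
              nrow(x$X), ncol(x$X), x$mode, x$modality,
              paste(sprintf("%s=%d", unique(x$provenance),
                            table(x$provenance)[unique(x$provenance)]),
                    collapse = ", ")))
  cat(sprintf("  classes: %d buy / %d no-buy\n", sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' SMOTE class balancing
#'
#' For each synthetic sample a minority point is drawn, one of its
#' `k` nearest minority neighbors (Euclidean) is drawn, and the new point is
#' placed uniformly on the segment between them. Generation repeats until
#' the minority count reaches `target_ratio` times the majority count.
#' Deterministic given `random_state`.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param k number of minority neighbors (default 3).
#' @param random_state RNG seed (default 42).
#' @param target_ratio desired minority/majority ratio after balancing.
#' @return List with balanced `X`, `y` and `synthetic` (logical marker, TRUE
#'   for generated rows, appended after the originals).
#' @export
smote_balance <- function(X, y, k = 3, random_state = 42, target_ratio = 1) {
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present")
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, length(y))))
  if (n_min <= k)
    stop("minority class has ", n_min, " samples but k = ", k,
         " neighbors are requested; use a smaller k")
  mi <- which(y == minority)
  Xm <- X[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  set.seed(random_state)
  base <- sample.int(length(mi), n_new, replace = TRUE)
  pick <- vapply(base, function(b) nn[b, sample.int(k, 1)], integer(1))
  u <- stats::runif(n_new)
  Xs <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, Xs),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new)))
}

# ---- base learners -------------------------------------------------------

prep_X <- function(X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

fit_base_rf <- function(X, y, num_trees, seed) {
  ranger::ranger(x = prep_X(X), y = factor(y, levels = c(0, 1)),
                 num.trees = num_trees, probability = TRUE,
                 num.threads = 1, seed = seed)
}

predict_base_rf <- function(fit, X) {
  stats::predict(fit, data = prep_X(X), num.threads = 1)$predictions[, "1"]
}

fit_base_xgb <- function(X, y, nrounds, seed, params) {
  dtrain <- xgboost::xgb.DMatrix(prep_X(X), label = y, nthread = 1)
  xgboost::xgb.train(params = c(list(objective = "binary:logistic",
                                     nthread = 1, tree_method = "hist",
                                     seed = seed), params),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_base_xgb <- function(fit, X) {
  stats::predict(fit, newdata = xgboost::xgb.DMatrix(prep_X(X), nthread = 1))
}

# classical gradient boosting: shallow trees, shrinkage 0.1, no regularization
gb_params <- list(max_depth = 3, eta = 0.1, lambda = 0, alpha = 0)
# XGBoost at library defaults
xgb_params <- list(max_depth = 6, eta = 0.3, lambda = 1, alpha = 0)

#' Stratified fold assignment
#'
#' Shuffled, seeded, class-preserving: each class is permuted and dealt
#' round-robin, so per-fold class proportions differ from the global ones by
#' at most one sample.
#'
#' @param y binary labels.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return Integer fold id (1..folds) per sample.
#' @export
stratified_folds <- function(y, folds = 10, seed = 42) {
  if (min(table(y)) < folds)
    stop("need at least `folds` samples per class for stratified folds")
  set.seed(seed)
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified group-wise fold assignment
#'
#' Like [stratified_folds()], but whole groups (e.g. all overlapping windows
#' segmented from one product trial) are kept in the same fold, stratifying
#' by the group's label. This prevents the leakage that window-level folding
#' incurs when windows from one trial share trial-specific structure.
#'
#' @param y binary labels per sample.
#' @param groups group identifier per sample (constant label within group).
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return Integer fold id (1..folds) per sample.
#' @export
stratified_group_folds <- function(y, groups, folds = 10, seed = 42) {
  gid <- as.character(groups)
  glab <- tapply(y, gid, function(v) v[1])
  if (min(table(glab)) < folds)
    stop("need at least `folds` groups per class for stratified group folds")
  gassign <- stratified_folds(as.integer(glab), folds, seed)
  names(gassign) <- names(glab)
  unname(gassign[gid])
}

#' Fit the stacking ensemble
#'
#' Three base classifiers — a random forest (265 trees), classical gradient
#' boosting (89 stages) and XGBoost (300 rounds) — feed a random forest meta
#' learner (100 trees). The meta-feature matrix Z has one column per base
#' learner and is built from out-of-fold base predictions under an internal
#' stratified, shuffled, seeded CV, so base and meta learners never see the
#' same information. Base learners are then refitted on all training data.
#'
#' @param X feature matrix (rows = windows).
#' @param y binary labels.
#' @param folds internal folds for the out-of-fold meta features.
#' @param seed seed controlling fold shuffling and every base/meta learner.
#' @param meta_input `"prob"` (default; Z holds positive-class
#'   probabilities) or `"label"` (hard 0/1 base predictions, the literal
#'   textbook construction).
#' @param n_rf,n_gb,n_xgb,n_meta tree/stage/round counts.
#' @return An object of class `stacking_model`.
#' @export
fit_stacking <- function(X, y, folds = 10, seed = 42,
                         meta_input = c("prob", "label"),
                         n_rf = 265, n_gb = 89, n_xgb = 300, n_meta = 100) {
  meta_input <- match.arg(meta_input)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (length(y) < folds) stop("need at least `folds` samples")
  X <- as.matrix(X)
  assign <- stratified_folds(y, folds, seed)
  Z <- matrix(NA_real_, length(y), 3,
              dimnames = list(NULL, c("P_RF", "P_GB", "P_XGB")))
  for (f in seq_len(folds)) {
    tr <- assign != f; ho <- !tr
    rf <- fit_base_rf(X[tr, , drop = FALSE], y[tr], n_rf, seed + f)
    gb <- fit_base_xgb(X[tr, , drop = FALSE], y[tr], n_gb, seed + f, gb_params)
    xg <- fit_base_xgb(X[tr, , drop = FALSE], y[tr], n_xgb, seed + f, xgb_params)
    Z[ho, 1] <- predict_base_rf(rf, X[ho, , drop = FALSE])
    Z[ho, 2] <- predict_base_xgb(gb, X[ho, , drop = FALSE])
    Z[ho, 3] <- predict_base_xgb(xg, X[ho, , drop = FALSE])
  }
  if (meta_input == "label") Z <- round(Z)
  meta <- fit_base_rf(Z, y, n_meta, seed)
  base <- list(rf = fit_base_rf(X, y, n_rf, seed),
               gb = fit_base_xgb(X, y, n_gb, seed, gb_params),
               xgb = fit_base_xgb(X, y, n_xgb, seed, xgb_params))
  structure(list(base = base, meta = meta, meta_input = meta_input,
                 Z = Z, fold_assign = assign, n_features = ncol(X),
                 seed = seed,
                 counts = c(rf = n_rf, gb = n_gb, xgb = n_xgb, meta = n_meta)),
            class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf(paste0("<stacking_model> base: RF(%d trees), GB(%d stages), ",
                     "XGB(%d rounds); meta: RF(%d trees) on %s meta-features\n"),
              x$counts["rf"], x$counts["gb"], x$counts["xgb"], x$counts["meta"],
              x$meta_input))
  cat(sprintf("  trained on %d features, %d windows\n", x$n_features,
              length(x$fold_assign)))
  invisible(x)
}

#' @export
summary.stacking_model <- function(object, ...) {
  cat("Out-of-fold meta-feature summary (Z):\n")
  print(summary(as.data.frame(object$Z)))
  invisible(object)
}

#' Predict from a stacking ensemble
#'
#' Each base model predicts, the predictions form the meta-feature row Z_x,
#' and the meta random forest votes; the returned score is the meta forest's
#' positive-class vote fraction.
#'
#' @param object a [fit_stacking()] model.
#' @param newdata feature matrix with the training width.
#' @param type `"class"` for 0/1 labels, `"prob"` for scores, `"both"` for a
#'   data frame with both.
#' @param ... unused.
#' @return Vector (or data frame for `"both"`) of predictions.
#' @export
predict.stacking_model <- function(object, newdata,
                                   type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(switch(type, class = integer(), prob = numeric(),
                  both = data.frame(class = integer(), prob = numeric())))
  }
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features but the model was trained ",
         "with ", object$n_features)
  Zx <- cbind(P_RF = predict_base_rf(object$base$rf, newdata),
              P_GB = predict_base_xgb(object$base$gb, newdata),
              P_XGB = predict_base_xgb(object$base$xgb, newdata))
  if (object$meta_input == "label") Zx <- round(Zx)
  prob <- predict_base_rf(object$meta, Zx)
  cls <- as.integer(prob >= 0.5)
  switch(type, class = cls, prob = prob,
         both = data.frame(class = cls, prob = prob))
}
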