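#' Experiment profiles
#'
#' Bundles of pipeline settings. `full_profile()` is the full-fidelity
#' configuration: flatten-level deep features (16,720-dim fusion), stratified
#' 10-fold CV inside and out, extractors retrained inside every training
#' fold for 50 epochs. `desk_profile()` is the scaled configuration the
#' package's own experiments and tests use on a single CPU: compact
#' last-dense deep features (64 + 84 dims), 5-fold CV, extractors trained
#' once per dataset (1 CNN-LSTM epoch / 5 LeNet epochs) on a stratified
#' subsample of at most 128 windows. The methods vignette discusses the
#' trade-off.
#'
#' @param seed seed forwarded to the extractor training configurations.
#' @return A named list of settings consumed by [run_experiment()].
#' @export
desk_profile <- function(seed = 42) {
  list(folds = 5, stacking_folds = 5, deep_layer = "last_dense",
       extractor_scope = "global", lenet_scope = "fold",
       extractor_subsample = 128,
       cnn = training_config(epochs = 1, batch_size = 32, loss = "mse",
                             seed = seed),
       lenet = training_config(epochs = 5, batch_size = 32, loss = "bce",
                               seed = seed))
}

#' @rdname desk_profile
#' @export
full_profile <- function(seed = 42) {
  list(folds = 10, stacking_folds = 10, deep_layer = "flatten",
       extractor_scope = "fold", lenet_scope = "fold",
       extractor_subsample = Inf,
       cnn = training_config(epochs = 50, batch_size = 16, loss = "mse",
                             seed = seed),
       lenet = training_config(epochs = 50, batch_size = 32, loss = "bce",
                               seed = seed))
}

#' Cross-validate a classifier over fused features
#'
#' Outer stratified k-fold CV (shuffled, seeded). In the default
#' `smote_scope = "fold"`, SMOTE sees only the training portion of each
#' fold; `"global"` balances the whole matrix first (the leakage-prone
#' variant some published pipelines use) and then folds the augmented data.
#' A `feature_fun` hook lets callers recompute features per fold (used for
#' leakage-safe per-fold extractor training); it receives the train and test
#' row indices and must return `list(train = , test = )` matrices, plus
#' optionally an attribute `"extractor_train_idx"` for provenance.
#'
#' @param fused a [fuse()] result (or any list with `X` and `y`).
#' @param folds outer fold count.
#' @param seed seed for fold shuffling and the stacking ensemble.
#' @param smote apply SMOTE balancing to training data?
#' @param smote_scope `"fold"` or `"global"`.
#' @param smote_k,smote_seed SMOTE neighbor count and random state.
#' @param stacking_folds internal folds for out-of-fold meta features.
#' @param meta_input `"prob"` or `"label"` (see [fit_stacking()]).
#' @param feature_fun optional per-fold feature recomputation hook.
#' @param group optional group id per row (e.g. the source trial); when
#'   given, folds are assigned group-wise via [stratified_group_folds()] so
#'   overlapping windows from one trial never straddle a fold boundary.
#' @param n_rf,n_gb,n_xgb,n_meta ensemble sizes, passed to [fit_stacking()].
#' @return An object of class `neurochoice_cv` with per-fold metrics
#'   (`fold_metrics`), pooled metrics over all held-out predictions
#'   (`pooled`), fold assignments, per-fold provenance and the configuration.
#' @export
crossvalidate <- function(fused, folds = 10, seed = 42, smote = TRUE,
                          smote_scope = c("fold", "global"), smote_k = 3,
                          smote_seed = 42, stacking_folds = 10,
                          meta_input = "prob", feature_fun = NULL,
                          group = NULL,
                          n_rf = 265, n_gb = 89, n_xgb = 300, n_meta = 100) {
  smote_scope <- match.arg(smote_scope)
  X <- fused$X; y <- as.integer(fused$y)
  if (smote && smote_scope == "global") {
    if (!is.null(feature_fun))
      stop("global SMOTE cannot be combined with per-fold feature recomputation")
    if (!is.null(group))
      stop("global SMOTE cannot be combined with grouped folds (synthetic rows have no group)")
    bal <- smote_balance(X, y, k = smote_k, random_state = smote_seed)
    X <- bal$X; y <- bal$y
  }
  assign <- if (is.null(group)) stratified_folds(y, folds, seed)
            else stratified_group_folds(y, group, folds, seed)
  fold_metrics <- vector("list", folds)
  provenance <- vector("list", folds)
  pred_all <- integer(length(y)); score_all <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    if (is.null(feature_fun)) {
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      ext_idx <- NULL
    } else {
      ft <- feature_fun(tr, te)
      Xtr <- ft$train; Xte <- ft$test
      ext_idx <- attr(ft, "extractor_train_idx")
    }
    ytr <- y[tr]
    n_syn <- 0L
    if (smote && smote_scope == "fold") {
      bal <- smote_balance(Xtr, ytr, k = smote_k, random_state = smote_seed)
      Xtr <- bal$X; ytr <- bal$y; n_syn <- sum(bal$synthetic)
    }
    model <- fit_stacking(Xtr, ytr, folds = stacking_folds, seed = seed,
                          meta_input = meta_input, n_rf = n_rf, n_gb = n_gb,
                          n_xgb = n_xgb, n_meta = n_meta)
    pred <- predict(model, Xte, type = "both")
    fold_metrics[[f]] <- compute_metrics(y[te], pred$class, pred$prob)
    provenance[[f]] <- list(train_idx = tr, test_idx = te,
                            extractor_train_idx = ext_idx,
                            n_synthetic = n_syn)
    pred_all[te] <- pred$class; score_all[te] <- pred$prob
  }
  pooled <- compute_metrics(y, pred_all, score_all)
  structure(list(fold_metrics = fold_metrics, pooled = pooled,
                 fold_assign = assign, provenance = provenance,
                 predictions = data.frame(y = y, pred = pred_all,
                                          score = score_all),
                 seed = seed,
                 config = list(folds = folds, smote = smote,
                               smote_scope = smote_scope, smote_k = smote_k,
                               smote_seed = smote_seed,
                               stacking_folds = stacking_folds,
                               meta_input = meta_input,
                               n_rf = n_rf, n_gb = n_gb, n_xgb = n_xgb,
                               n_meta = n_meta, grouped = !is.null(group))),
            class = "neurochoice_cv")
}

#' @export
print.neurochoice_cv <- function(x, ...) {
  acc <- vapply(x$fold_metrics, function(m) m$accuracy, numeric(1))
  auc <- vapply(x$fold_metrics, function(m) m$auc, numeric(1))
  cat(sprintf("<neurochoice_cv> %d folds: accuracy %.4f +/- %.4f",
              length(acc), mean(acc), stats::sd(acc)))
  if (all(is.finite(auc))) cat(sprintf(", AUC %.4f +/- %.4f", mean(auc),
                                       stats::sd(auc)))
  cat("\n  pooled: ")
  print(x$pooled)
  invisible(x)
}

#' @export
summary.neurochoice_cv <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$fold_metrics, metrics_row))
  cbind(fold = seq_len(nrow(per_fold)), per_fold)
}

# merge per-subject nc_windows objects (windows, info, gaze plots, fixations)
combine_windows <- function(ws_list) {
  out <- list(windows = do.call(c, lapply(ws_list, `[[`, "windows")),
              info = do.call(rbind, lapply(ws_list, `[[`, "info")))
  if (!is.null(ws_list[[1]]$gaze_plots))
    out$gaze_plots <- do.call(c, lapply(ws_list, `[[`, "gaze_plots"))
  if (!is.null(ws_list[[1]]$fixations))
    out$fixations <- do.call(c, lapply(ws_list, `[[`, "fixations"))
  structure(out, class = "nc_windows")
}

# stratified subsample of at most n_max window indices (both classes kept)
subsample_idx <- function(labels, n_max, seed) {
  n <- length(labels)
  if (n <= n_max) return(seq_len(n))
  set.seed(seed)
  idx <- unlist(lapply(unique(labels), function(cl) {
    cand <- which(labels == cl)
    sample(cand, max(2L, round(n_max * length(cand) / n)))
  }))
  sort(idx)
}

#' Preprocess recordings and compute every feature block once
#'
#' Runs both preprocessing chains, aligns the window streams and computes
#' all four feature blocks (EEG-deep, ET-deep, EEG-hand, ET-hand) with
#' globally trained extractors. The result can be passed to
#' [run_experiment()] (`features =`) so that several ablation arms (mode /
#' modality combinations) reuse one feature computation, which is how the
#' package's own experiment grids are run.
#'
#' @inheritParams run_experiment
#' @return An object of class `nc_feature_set` with `blocks`, `labels`,
#'   `subjects`, `extractor_train_idx` and the extractor models.
#' @export
compute_feature_set <- function(recordings, profile = desk_profile(),
                                seed = 42, eeg_cfg = cleaner_config(),
                                et_cfg = gaze_config(), asr = TRUE,
                                force = TRUE) {
  eeg_all <- combine_windows(lapply(recordings, function(r)
    preprocess_eeg(r$eeg, eeg_cfg, asr = asr, force = force)))
  et_all <- combine_windows(lapply(recordings, function(r)
    preprocess_et(r$et, et_cfg)))
  al <- align_windows(eeg_all, et_all)
  eeg_w <- eeg_all$windows[al$eeg_idx]
  plots <- et_all$gaze_plots[al$et_idx]
  fixes <- et_all$fixations[al$et_idx]
  labels <- al$labels
  n <- length(labels)
  sub <- subsample_idx(labels, profile$extractor_subsample, seed)
  cnn <- train_extractor(build_cnn_lstm(seed = seed), eeg_w[sub], labels[sub],
                         profile$cnn)
  lenet <- train_extractor(build_lenet5(seed = seed), plots[sub], labels[sub],
                           profile$lenet)
  blocks <- list(
    eeg_deep = extract_features(cnn, eeg_w, layer = profile$deep_layer),
    et_deep = extract_features(lenet, plots, layer = profile$deep_layer),
    eeg_hand = t(vapply(eeg_w, function(w)
      eeg_hand_features(w, fs = recordings[[1]]$eeg$fs,
                        dwt_level = eeg_cfg$force_level,
                        wavelet = eeg_cfg$force_wavelet),
      numeric(nrow(eeg_w[[1]]) * (4 + 5 + 2 * (eeg_cfg$force_level + 1))))),
    et_hand = {
      th <- t(vapply(fixes, function(fx) as.numeric(et_hand_features(fx)),
                     numeric(4)))
      colnames(th) <- c("et_fix_duration_mean", "et_fix_count",
                        "et_saccade_amp_mean", "et_saccade_count")
      th
    })
  structure(list(blocks = blocks, labels = labels, subjects = al$subjects,
                 trial_key = al$trial_key, extractor_train_idx = sub,
                 models = list(cnn = cnn, lenet = lenet), plots = plots,
                 deep_layer = profile$deep_layer),
            class = "nc_feature_set")
}

#' @export
print.nc_feature_set <- function(x, ...) {
  cat(sprintf("<nc_feature_set> %d windows; blocks: %s\n", length(x$labels),
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, ncol, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Run the full multimodal pipeline on a set of recordings
#'
#' Preprocesses every subject's EEG (band-pass, ASR, windowing, wavelet
#' cleaning) and gaze stream (interpolation, windowing, gaze plots,
#' fixations), aligns the two window streams, computes handcrafted and deep
#' features as the mode/modality demand, fuses them, and evaluates the
#' SMOTE-balanced stacking ensemble under stratified cross-validation.
#' The (`mode`, `modality`) grid reproduces the ablation axes
#' (handcrafted-only vs deep-only vs both; EEG-only vs ET-only vs
#' multimodal).
#'
#' @param recordings list of per-subject `list(eeg =, et =)` recordings,
#'   e.g. from [generate_recordings()].
#' @param mode `"full"`, `"deep_only"` or `"hand_only"`.
#' @param modality `"both"`, `"eeg"` or `"et"`.
#' @param profile settings list from [desk_profile()] or [full_profile()].
#' @param seed master seed for extractor training, fold shuffling and the
#'   ensemble.
#' @param eeg_cfg,et_cfg preprocessing configurations.
#' @param asr,force EEG cleaning stage switches (for "not preprocessed"
#'   ablations).
#' @param smote,smote_scope,meta_input forwarded to [crossvalidate()].
#' @param features optional precomputed [compute_feature_set()] (requires
#'   globally trained extractors); lets several ablation arms share one
#'   feature computation.
#' @return A `neurochoice_cv` object; its `config` element records the full
#'   experiment configuration, and `fused` holds the fused feature matrix
#'   when extractors are trained globally.
#' @export
run_experiment <- function(recordings, mode = c("full", "deep_only", "hand_only"),
                           modality = c("both", "eeg", "et"),
                           profile = desk_profile(), seed = 42,
                           eeg_cfg = cleaner_config(), et_cfg = gaze_config(),
                           asr = TRUE, force = TRUE, smote = TRUE,
                           smote_scope = "fold", meta_input = "prob",
                           features = NULL) {
  mode <- match.arg(mode)
  modality <- match.arg(modality)
  if (is.null(features) && identical(profile$extractor_scope, "global"))
    features <- compute_feature_set(recordings, profile, seed, eeg_cfg,
                                    et_cfg, asr, force)
  if (!is.null(features)) {
    stopifnot(inherits(features, "nc_feature_set"))
    need_et_deep <- mode %in% c("full", "deep_only") &&
      modality %in% c("both", "et")
    labels <- features$labels
    fold_lenet <- need_et_deep && identical(profile$lenet_scope, "fold")
    fused <- fuse(features$blocks, labels, subjects = features$subjects,
                  mode = mode, modality = modality)
    ffun <- NULL
    if (fold_lenet) {
      # the gaze-plot extractor memorizes individual plots easily, so it is
      # always retrained inside the training fold; cached blocks carry the
      # remaining (leak-free) features
      static <- features$blocks[setdiff(unique(fused$provenance), "et_deep")]
      ffun <- function(tr, te) {
        sub <- tr[subsample_idx(labels[tr], profile$extractor_subsample, seed)]
        lenet <- train_extractor(build_lenet5(seed = seed),
                                 features$plots[sub], labels[sub],
                                 profile$lenet)
        etd <- extract_features(lenet, features$plots[c(tr, te)],
                                layer = profile$deep_layer)
        rows <- function(idx, which_half) {
          bl <- lapply(static, function(b) b[idx, , drop = FALSE])
          bl$et_deep <- etd[which_half, , drop = FALSE]
          fuse(bl, labels[idx], mode = mode, modality = modality)$X
        }
        structure(list(train = rows(tr, seq_along(tr)),
                       test = rows(te, length(tr) + seq_along(te))),
                  extractor_train_idx = sub)
      }
    }
    cv <- crossvalidate(fused, folds = profile$folds, seed = seed,
                        smote = smote, smote_scope = smote_scope,
                        stacking_folds = profile$stacking_folds,
                        meta_input = meta_input, group = features$trial_key,
                        feature_fun = ffun)
    cv$fused <- fused
    if (is.null(ffun)) cv$extractor_train_idx <- features$extractor_train_idx
    cv$config <- c(cv$config,
                   list(mode = mode, modality = modality,
                        deep_layer = features$deep_layer,
                        extractor_scope = "global",
                        lenet_scope = if (fold_lenet) "fold" else "global",
                        asr = asr, force = force,
                        n_windows = length(labels)))
    return(cv)
  }
  need_eeg <- modality %in% c("both", "eeg")
  need_et <- modality %in% c("both", "et")
  need_deep <- mode %in% c("full", "deep_only")
  need_hand <- mode %in% c("full", "hand_only")

  eeg_all <- combine_windows(lapply(recordings, function(r)
    preprocess_eeg(r$eeg, eeg_cfg, asr = asr, force = force)))
  et_all <- combine_windows(lapply(recordings, function(r)
    preprocess_et(r$et, et_cfg)))
  al <- align_windows(eeg_all, et_all)
  eeg_w <- eeg_all$windows[al$eeg_idx]
  plots <- et_all$gaze_plots[al$et_idx]
  fixes <- et_all$fixations[al$et_idx]
  labels <- al$labels
  n <- length(labels)

  blocks_static <- list()
  if (need_hand && need_eeg) {
    eh <- t(vapply(eeg_w, function(w)
      eeg_hand_features(w, fs = recordings[[1]]$eeg$fs,
                        dwt_level = eeg_cfg$force_level,
                        wavelet = eeg_cfg$force_wavelet),
      numeric(nrow(eeg_w[[1]]) * (4 + 5 + 2 * (eeg_cfg$force_level + 1)))))
    blocks_static$eeg_hand <- eh
  }
  if (need_hand && need_et) {
    th <- t(vapply(fixes, function(fx) as.numeric(et_hand_features(fx)),
                   numeric(4)))
    colnames(th) <- c("et_fix_duration_mean", "et_fix_count",
                      "et_saccade_amp_mean", "et_saccade_count")
    blocks_static$et_hand <- th
  }

  train_deep <- function(idx) {
    sub <- idx[subsample_idx(labels[idx], profile$extractor_subsample, seed)]
    out <- list()
    if (need_deep && need_eeg) {
      m <- build_cnn_lstm(seed = seed)
      out$cnn <- train_extractor(m, eeg_w[sub], labels[sub], profile$cnn)
    }
    if (need_deep && need_et) {
      m <- build_lenet5(seed = seed)
      out$lenet <- train_extractor(m, plots[sub], labels[sub], profile$lenet)
    }
    attr(out, "train_idx") <- sub
    out
  }
  deep_blocks <- function(models, idx) {
    out <- list()
    if (!is.null(models$cnn))
      out$eeg_deep <- extract_features(models$cnn, eeg_w[idx],
                                       layer = profile$deep_layer)
    if (!is.null(models$lenet))
      out$et_deep <- extract_features(models$lenet, plots[idx],
                                      layer = profile$deep_layer)
    out
  }

  if (!need_deep || profile$extractor_scope == "global") {
    models <- if (need_deep) train_deep(seq_len(n)) else list()
    blocks <- c(deep_blocks(models, seq_len(n)), blocks_static)
    fused <- fuse(blocks, labels, subjects = al$subjects, mode = mode,
                  modality = modality)
    cv <- crossvalidate(fused, folds = profile$folds, seed = seed,
                        smote = smote, smote_scope = smote_scope,
                        stacking_folds = profile$stacking_folds,
                        meta_input = meta_input, group = al$trial_key)
    cv$fused <- fused
    if (need_deep) cv$extractor_train_idx <- attr(models, "train_idx")
  } else {
    # leakage-safe default: extractors are retrained inside every fold on
    # that fold's training rows only
    fused <- list(X = matrix(0, n, 1), y = labels)   # placeholder for folds
    ffun <- function(tr, te) {
      models <- train_deep(tr)
      btr <- c(deep_blocks(models, tr), lapply(blocks_static, function(b)
        b[tr, , drop = FALSE]))
      bte <- c(deep_blocks(models, te), lapply(blocks_static, function(b)
        b[te, , drop = FALSE]))
      ftr <- fuse(btr, labels[tr], mode = mode, modality = modality)
      fte <- fuse(bte, labels[te], mode = mode, modality = modality)
      structure(list(train = ftr$X, test = fte$X),
                extractor_train_idx = attr(models, "train_idx"))
    }
    cv <- crossvalidate(fused, folds = profile$folds, seed = seed,
                        smote = smote, smote_scope = smote_scope,
                        stacking_folds = profile$stacking_folds,
                        meta_input = meta_input, feature_fun = ffun,
                        group = al$trial_key)
  }
  cv$config <- c(cv$config,
                 list(mode = mode, modality = modality,
                      deep_layer = profile$deep_layer,
                      extractor_scope = if (need_deep) profile$extractor_scope
                                        else "none",
                      asr = asr, force = force, n_windows = n))
  cv
}
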