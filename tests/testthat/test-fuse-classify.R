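mk_ws <- function(subject, trials, per_trial, kind = "eeg") {
  windows <- list(); info <- list()
  for (tr in seq_along(per_trial)) {
    for (oi in seq_len(per_trial[tr])) {
      windows[[length(windows) + 1]] <-
        if (kind == "eeg") matrix(0, 19, 300) else matrix(0, 120, 2)
      info[[length(info) + 1]] <- data.frame(
        subject = subject, trial = trials[tr], ordinal = oi, start = 0L,
        label = tr %% 2L, stringsAsFactors = FALSE)
    }
  }
  structure(list(windows = windows, info = do.call(rbind, info)),
            class = "nc_windows")
}

test_that("window alignment pairs by (trial, ordinal) and truncates honestly", {
  e <- mk_ws("S01", 1:2, c(7, 7))
  t7 <- mk_ws("S01", 1:2, c(7, 7), "et")
  al <- align_windows(e, t7)
  expect_length(al$eeg_idx, 14)
  expect_identical(al$labels, e$info$label)

  t5 <- mk_ws("S01", 1:2, c(7, 5), "et")
  expect_warning(al2 <- align_windows(e, t5), "truncating to 5")
  expect_length(al2$eeg_idx, 12)

  t_other <- mk_ws("S01", 3:4, c(7, 7), "et")
  expect_warning(al3 <- align_windows(e, t_other), "one modality only")
  expect_length(al3$eeg_idx, 0)
})

test_that("fusion concatenates blocks in order with full provenance", {
  n <- 10
  blocks <- list(eeg_deep = matrix(1, n, 14016), et_deep = matrix(2, n, 2704),
                 eeg_hand = matrix(3, n, 361), et_hand = matrix(4, n, 4))
  y <- rep(c(0, 1), 5)
  fd <- fuse(blocks, y, mode = "deep_only")
  expect_identical(ncol(fd$X), 16720L)            # 14016 + 2704
  fh <- fuse(blocks, y, mode = "hand_only")
  expect_identical(ncol(fh$X), 365L)              # 361 + 4
  ff <- fuse(blocks, y, mode = "full")
  expect_identical(ncol(ff$X), 16720L + 365L)
  expect_identical(as.integer(table(ff$provenance)[c("eeg_deep", "et_deep",
                                                     "eeg_hand", "et_hand")]),
                   c(14016L, 2704L, 361L, 4L))
  # provenance covers all columns exactly once, in the documented order
  expect_identical(unique(ff$provenance),
                   c("eeg_deep", "et_deep", "eeg_hand", "et_hand"))
  # modality filters
  expect_identical(ncol(fuse(blocks, y, mode = "full", modality = "eeg")$X),
                   14016L + 361L)
  expect_identical(ncol(fuse(blocks, y, mode = "full", modality = "et")$X),
                   2704L + 4L)

  blocks$eeg_hand[1, 1] <- NaN
  expect_error(fuse(blocks, y, mode = "hand_only"), "NaN")
  expect_error(fuse(blocks[1], rep(0:1, 3)), "labels")
})

test_that("SMOTE balances exactly, interpolates on minority segments, and is deterministic", {
  set.seed(71)
  X <- rbind(matrix(rnorm(10 * 2, 0, 1), 10, 2),
             matrix(rnorm(30 * 2, 5, 1), 30, 2))
  y <- c(rep(1, 10), rep(0, 30))
  out <- smote_balance(X, y, k = 3, random_state = 42)
  expect_identical(as.integer(table(out$y)), c(30L, 30L))
  expect_identical(sum(out$synthetic), 20L)

  # determinism
  out2 <- smote_balance(X, y, k = 3, random_state = 42)
  expect_identical(out$X, out2$X)

  # 2-D oracle: every synthetic point lies on a segment between a minority
  # point and one of its k nearest minority neighbors
  Xm <- X[y == 1, ]
  D <- as.matrix(dist(Xm)); diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[1:3]))
  on_segment <- function(p) {
    for (b in seq_len(nrow(Xm))) for (j in nn[b, ]) {
      a <- Xm[b, ]; c <- Xm[j, ]
      if (abs(sqrt(sum((p - a)^2)) + sqrt(sum((p - c)^2)) -
              sqrt(sum((c - a)^2))) < 1e-8) return(TRUE)
    }
    FALSE
  }
  syn <- out$X[out$synthetic, , drop = FALSE]
  expect_true(all(apply(syn, 1, on_segment)))

  # degenerate: identical minority points collapse the segments
  Xc <- rbind(matrix(1, 5, 2), matrix(rnorm(20 * 2, 10), 20, 2))
  yc <- c(rep(1, 5), rep(0, 20))
  outc <- smote_balance(Xc, yc, k = 3, random_state = 1)
  expect_true(all(outc$X[outc$synthetic, ] == 1))

  expect_error(smote_balance(X[c(1:3, 11:40), ], y[c(1:3, 11:40)], k = 3),
               "smaller k")
  # already balanced: untouched
  outb <- smote_balance(X[1:20, ], rep(c(0, 1), each = 10))
  expect_identical(nrow(outb$X), 20L)
})

test_that("stratified folds preserve class proportions and respect groups", {
  y <- rep(c(1, 0), c(40, 60))
  f <- stratified_folds(y, 10, seed = 42)
  for (k in 1:10) {
    expect_identical(sum(y[f == k] == 1), 4L)
    expect_identical(sum(y[f == k] == 0), 6L)
  }
  expect_identical(stratified_folds(y, 10, seed = 42),
                   stratified_folds(y, 10, seed = 42))
  expect_false(identical(stratified_folds(y, 10, seed = 1), f))

  g <- rep(1:20, each = 5)
  yg <- rep(rep(c(0, 1), 10), each = 5)
  fg <- stratified_group_folds(yg, g, folds = 5, seed = 42)
  expect_true(all(tapply(fg, g, function(v) length(unique(v))) == 1))
  for (k in 1:5) expect_identical(mean(yg[fg == k]), 0.5)
})

test_that("stacking learns a separable problem and exposes the 3-column meta structure", {
  set.seed(72)
  X <- rbind(matrix(rnorm(100 * 5, 0), 100, 5), matrix(rnorm(100 * 5, 6), 100, 5))
  y <- rep(c(0L, 1L), each = 100)
  m <- fit_stacking(X, y, folds = 10, seed = 42)
  expect_identical(colnames(m$Z), c("P_RF", "P_GB", "P_XGB"))
  expect_identical(ncol(m$Z), 3L)
  expect_false(anyNA(m$Z))
  pred <- predict(m, X)
  expect_identical(pred, y)                       # training accuracy 1.0
  # a training row keeps its training label
  expect_identical(predict(m, X[5, , drop = FALSE]), 0L)
  expect_identical(predict(m, X[150, , drop = FALSE]), 1L)
  pr <- predict(m, X, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))

  expect_error(predict(m, X[, 1:3]), "features")
  expect_length(predict(m, X[0, , drop = FALSE]), 0L)
  expect_error(fit_stacking(X, rep(1, 200)), "both classes")
})

test_that("constant base inputs collapse the stack to the majority constant", {
  X <- matrix(0, 40, 3)
  y <- rep(c(1, 0), c(28, 12))
  m <- fit_stacking(X, y, folds = 5, seed = 42)
  expect_true(all(predict(m, X) == 1L))
})

test_that("label-mode meta features are hard votes as in the textbook construction", {
  set.seed(73)
  X <- rbind(matrix(rnorm(60 * 4, 0), 60, 4), matrix(rnorm(60 * 4, 5), 60, 4))
  y <- rep(c(0L, 1L), each = 60)
  m <- fit_stacking(X, y, folds = 5, seed = 42, meta_input = "label")
  expect_true(all(m$Z %in% c(0, 1)))
  expect_identical(predict(m, X), y)
})

test_that("cross-validation is leakage-free, stratified and reproducible", {
  set.seed(74)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- rep(c(1, 0), c(40, 60))
  fused <- list(X = X, y = y)
  cv <- crossvalidate(fused, folds = 5, seed = 42, stacking_folds = 5,
                      n_rf = 50, n_gb = 20, n_xgb = 30, n_meta = 50)
  # stratification contract: each test fold holds 8 buy / 12 no-buy
  for (f in 1:5) {
    te <- which(cv$fold_assign == f)
    expect_identical(sum(y[te] == 1), 8L)
    expect_identical(sum(y[te] == 0), 12L)
  }
  # provenance: no test row ever appears in its fold's training set
  for (f in 1:5) {
    p <- cv$provenance[[f]]
    expect_length(intersect(p$train_idx, p$test_idx), 0L)
    expect_gt(p$n_synthetic, 0L)                # SMOTE ran on the train fold
  }
  cv2 <- crossvalidate(fused, folds = 5, seed = 42, stacking_folds = 5,
                       n_rf = 50, n_gb = 20, n_xgb = 30, n_meta = 50)
  expect_identical(cv$fold_assign, cv2$fold_assign)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("per-fold feature recomputation confines extractor training to the fold", {
  set.seed(75)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c(0, 1), 30)
  seen <- list()
  ffun <- function(tr, te) {
    seen[[length(seen) + 1]] <<- list(tr = tr, te = te)
    structure(list(train = X[tr, , drop = FALSE], test = X[te, , drop = FALSE]),
              extractor_train_idx = tr)
  }
  cv <- crossvalidate(list(X = X, y = y), folds = 3, seed = 1,
                      stacking_folds = 3, feature_fun = ffun,
                      n_rf = 20, n_gb = 10, n_xgb = 10, n_meta = 20)
  for (f in seq_along(cv$provenance)) {
    p <- cv$provenance[[f]]
    expect_identical(p$extractor_train_idx, p$train_idx)
    expect_length(intersect(p$extractor_train_idx, p$test_idx), 0L)
  }
})
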