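test_that("CNN-LSTM layer table reproduces the declared shapes and parameter counts", {
  m <- build_cnn_lstm()
  lt <- m$layer_table
  get <- function(layer, col) lt[lt$layer == layer, col]
  expect_identical(get("input", "output_shape"), "(19, 300, 1)")
  expect_identical(get("conv2d_1", "output_shape"), "(17, 298, 32)")
  expect_identical(get("conv2d_1", "params"), 320L)        # 32*(3*3*1+1)
  expect_identical(get("maxpool_1", "output_shape"), "(8, 149, 32)")
  expect_identical(get("conv2d_2", "output_shape"), "(6, 147, 64)")
  expect_identical(get("conv2d_2", "params"), 18496L)      # 64*(3*3*32+1)
  expect_identical(get("maxpool_2", "output_shape"), "(3, 73, 64)")
  expect_identical(get("flatten", "output_shape"), "(14016)")
  expect_identical(get("dense_1", "params"), 8320L)        # 128*(64+1)
  expect_identical(get("dense_2", "params"), 8256L)        # 64*(128+1)
  # standard 4*H*(in + H + 1) LSTM count; see docs for the printed-figure
  # discrepancy, which is not asserted
  expect_identical(get("lstm", "params"), 16896L)
  expect_error(build_cnn_lstm(input_shape = c(21, 300)), "19 x 300")
})

test_that("LeNet-5 layer table reproduces the declared shapes and parameter counts", {
  m <- build_lenet5()
  lt <- m$layer_table
  get <- function(layer, col) lt[lt$layer == layer, col]
  expect_identical(get("conv2d_1", "output_shape"), "(60, 60, 6)")
  expect_identical(get("conv2d_1", "params"), 156L)        # 6*(5*5*1+1)
  expect_identical(get("conv2d_2", "output_shape"), "(26, 26, 16)")
  expect_identical(get("conv2d_2", "params"), 2416L)       # 16*(5*5*6+1)
  expect_identical(get("maxpool_2", "output_shape"), "(13, 13, 16)")
  expect_identical(get("flatten", "output_shape"), "(2704)")
  expect_error(build_lenet5(input_shape = c(32, 32)), "64 x 64")
})

test_that("feature extraction widths follow the layer choice and inputs are validated", {
  set.seed(61)
  wins <- lapply(1:3, function(i) matrix(rnorm(19 * 300), 19, 300))
  m <- build_cnn_lstm(seed = 2)
  expect_identical(dim(extract_features(m, wins, "flatten")), c(3L, 14016L))
  expect_identical(dim(extract_features(m, wins, "last_dense")), c(3L, 64L))

  plots <- lapply(1:3, function(i) matrix(runif(64 * 64, 0, 255), 64, 64))
  ml <- build_lenet5(seed = 2)
  expect_identical(dim(extract_features(ml, plots, "flatten")), c(3L, 2704L))
  expect_identical(dim(extract_features(ml, plots, "last_dense")), c(3L, 84L))

  expect_error(extract_features(m, plots), "does not match")
  expect_error(extract_features(m, wins, "bogus"))
})

test_that("zero input yields finite features (bias pattern only)", {
  z <- list(matrix(0, 19, 300))
  f <- extract_features(build_cnn_lstm(seed = 3), z, "flatten")
  expect_true(all(is.finite(f)))
  zl <- list(matrix(0, 64, 64))
  fl <- extract_features(build_lenet5(seed = 3), zl, "last_dense")
  expect_true(all(is.finite(fl)))
})

test_that("training is deterministic, inert at lr = 0, and rejects one-class labels", {
  set.seed(62)
  plots <- lapply(1:12, function(i) matrix(runif(64 * 64, 0, 255), 64, 64))
  labs <- rep(c(0, 1), 6)
  cfg <- training_config(epochs = 2, batch_size = 4, loss = "bce", seed = 5)
  m1 <- train_extractor(build_lenet5(seed = 7), plots, labs, cfg)
  m2 <- train_extractor(build_lenet5(seed = 7), plots, labs, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_history, m2$loss_history)

  cfg0 <- training_config(epochs = 3, batch_size = 4, lr = 0, seed = 5)
  m0 <- build_lenet5(seed = 7)
  mt <- train_extractor(m0, plots, labs, cfg0)
  # the engine computes in single precision; the round-trip quantizes
  expect_equal(mt$weights, m0$weights, tolerance = 1e-6)

  expect_error(train_extractor(build_lenet5(), plots, rep(1, 12), cfg),
               "single class")
})

test_that("LeNet-5 training loss decreases on separable gaze plots across seeds", {
  set.seed(63)
  mk_plot <- function(lab) {
    img <- matrix(0, 64, 64)
    pts <- if (lab == 1) cbind(sample(5:20, 25, TRUE), sample(5:20, 25, TRUE))
           else cbind(sample(40:60, 25, TRUE), sample(40:60, 25, TRUE))
    img[pts] <- 255
    img
  }
  labs <- rep(c(0, 1), 20)
  plots <- lapply(labs, mk_plot)
  dec <- vapply(1:5, function(s) {
    m <- train_extractor(build_lenet5(seed = s), plots, labs,
                         training_config(epochs = 5, batch_size = 8,
                                         loss = "bce", seed = s))
    all(diff(m$loss_history) < 0)
  }, logical(1))
  expect_gte(sum(dec), 4)
})

test_that("CNN-LSTM training loss decreases on alpha-separable EEG windows", {
  set.seed(64)
  tt <- (0:299) / 300
  mk_win <- function(lab) {
    matrix(rnorm(19 * 300, 0, 3), 19, 300) +
      (if (lab == 1) 8 else 1) * matrix(rep(sin(2 * pi * 10 * tt), 19), 19,
                                        byrow = TRUE)
  }
  labs <- rep(c(0, 1), 16)
  wins <- lapply(labs, mk_win)
  dec <- vapply(1:2, function(s) {
    m <- train_extractor(build_cnn_lstm(seed = s), wins, labs,
                         training_config(epochs = 3, batch_size = 16,
                                         loss = "mse", seed = s))
    all(diff(m$loss_history) < 0)
  }, logical(1))
  expect_gte(sum(dec), 1)
})
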