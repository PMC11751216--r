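#' Training configuration for the deep feature extractors
#'
#' Both extractors are trained with Adam against a 1-unit sigmoid head on
#' the window label; the head is discarded for feature extraction. The
#' CNN-LSTM uses mean squared error on the sigmoid output by default, the
#' LeNet-5 binary cross-entropy, both switchable.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (eta).
#' @param beta1,beta2 Adam moment decay rates.
#' @param eps Adam stabilizer.
#' @param loss `"mse"` or `"bce"`.
#' @param seed seed for weight initialization and epoch shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 50, batch_size = 32, lr = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            loss = c("mse", "bce"), seed = 42) {
  loss <- match.arg(loss)
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in (0, 1)")
  if (lr < 0) stop("learning rate must be >= 0")
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps, loss = loss,
                 seed = seed),
            class = "training_config")
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build the CNN-LSTM EEG feature extractor
#'
#' Architecture (input 19 x 300 x 1): 3x3 valid conv with 32 filters, 2x2
#' max pool, 3x3 conv with 64 filters, 2x2 max pool, flatten (14,016),
#' reshape to a 14,016-step sequence of scalars, LSTM with 64 units, dense
#' 128, dense 64, and a 1-unit sigmoid training head. Features are taken at
#' the flatten layer (14,016-dim) or the last dense layer (64-dim).
#'
#' The LSTM's parameter count follows the standard `4 * H * (in + H + 1)`
#' formula (16,896 here); see the methods vignette for why a smaller printed
#' figure circulating for this architecture is not reproducible from the
#' declared shapes.
#'
#' @param input_shape `c(channels, samples)`; must be `c(19, 300)`.
#' @param seed weight initialization seed.
#' @return An object of class `cnn_lstm_model` with elements `weights`,
#'   `layer_table`, `fitted`, `loss_history`.
#' @export
build_cnn_lstm <- function(input_shape = c(19, 300), seed = 42) {
  if (!identical(as.integer(input_shape), c(19L, 300L)))
    stop("layer `input`: the CNN-LSTM is defined for 19 x 300 windows, got ",
         paste(input_shape, collapse = " x "))
  set.seed(seed)
  H <- 64
  weights <- list(
    conv1_W = glorot(32, 9, 9, 9 * 32), conv1_b = matrix(0, 32, 1),
    conv2_W = glorot(64, 288, 288, 9 * 64), conv2_b = matrix(0, 64, 1),
    lstm_Wx = glorot(4 * H, 1, 1 + H, H),
    lstm_Wh = glorot(4 * H, H, 1 + H, H),
    lstm_b = rbind(matrix(0, H, 1), matrix(1, H, 1), matrix(0, 2 * H, 1)),
    fc1_W = glorot(128, 64, 64, 128), fc1_b = matrix(0, 128, 1),
    fc2_W = glorot(64, 128, 128, 64), fc2_b = matrix(0, 64, 1),
    out_W = glorot(1, 64, 64, 1), out_b = matrix(0, 1, 1))
  lt <- data.frame(
    layer = c("input", "conv2d_1", "maxpool_1", "conv2d_2", "maxpool_2",
              "flatten", "reshape", "lstm", "dense_1", "dense_2", "sigmoid_head"),
    output_shape = c("(19, 300, 1)", "(17, 298, 32)", "(8, 149, 32)",
                     "(6, 147, 64)", "(3, 73, 64)", "(14016)", "(14016, 1)",
                     "(64)", "(128)", "(64)", "(1)"),
    params = c(0L,
               length(weights$conv1_W) + length(weights$conv1_b),
               0L,
               length(weights$conv2_W) + length(weights$conv2_b),
               0L, 0L, 0L,
               length(weights$lstm_Wx) + length(weights$lstm_Wh) +
                 length(weights$lstm_b),
               length(weights$fc1_W) + length(weights$fc1_b),
               length(weights$fc2_W) + length(weights$fc2_b),
               length(weights$out_W) + length(weights$out_b)),
    stringsAsFactors = FALSE)
  structure(list(weights = weights, layer_table = lt, fitted = FALSE,
                 loss_history = numeric(), input_shape = c(19L, 300L),
                 kind = "cnn_lstm"),
            class = c("cnn_lstm_model", "nc_extractor"))
}

#' Build the LeNet-5 gaze-plot feature extractor
#'
#' Architecture (input 64 x 64 x 1): 5x5 valid conv with 6 filters, 2x2 max
#' pool, 5x5 conv with 16 filters, 2x2 max pool, flatten (2,704), dense 120,
#' dense 84, 1-unit sigmoid head. Features are taken at the flatten layer
#' (2,704-dim) or the last dense layer (84-dim). With a single-channel input
#' the first convolution has 156 parameters (`6 * (5*5*1 + 1)`).
#'
#' @param input_shape canvas `c(height, width)`; must be `c(64, 64)`.
#' @param seed weight initialization seed.
#' @return An object of class `lenet5_model`.
#' @export
build_lenet5 <- function(input_shape = c(64, 64), seed = 42) {
  if (!identical(as.integer(input_shape), c(64L, 64L)))
    stop("layer `input`: LeNet-5 is defined for a 64 x 64 canvas, got ",
         paste(input_shape, collapse = " x "))
  set.seed(seed)
  weights <- list(
    conv1_W = glorot(6, 25, 25, 25 * 6), conv1_b = matrix(0, 6, 1),
    conv2_W = glorot(16, 150, 150, 25 * 16), conv2_b = matrix(0, 16, 1),
    fc1_W = glorot(120, 2704, 2704, 120), fc1_b = matrix(0, 120, 1),
    fc2_W = glorot(84, 120, 120, 84), fc2_b = matrix(0, 84, 1),
    out_W = glorot(1, 84, 84, 1), out_b = matrix(0, 1, 1))
  lt <- data.frame(
    layer = c("input", "conv2d_1", "maxpool_1", "conv2d_2", "maxpool_2",
              "flatten", "dense_1", "dense_2", "sigmoid_head"),
    output_shape = c("(64, 64, 1)", "(60, 60, 6)", "(30, 30, 6)",
                     "(26, 26, 16)", "(13, 13, 16)", "(2704)", "(120)",
                     "(84)", "(1)"),
    params = c(0L,
               length(weights$conv1_W) + length(weights$conv1_b),
               0L,
               length(weights$conv2_W) + length(weights$conv2_b),
               0L, 0L,
               length(weights$fc1_W) + length(weights$fc1_b),
               length(weights$fc2_W) + length(weights$fc2_b),
               length(weights$out_W) + length(weights$out_b)),
    stringsAsFactors = FALSE)
  structure(list(weights = weights, layer_table = lt, fitted = FALSE,
                 loss_history = numeric(), input_shape = c(64L, 64L),
                 kind = "lenet5"),
            class = c("lenet5_model", "nc_extractor"))
}

#' @export
print.nc_extractor <- function(x, ...) {
  cat(sprintf("<%s> %s, total params %s\n", class(x)[1],
              if (x$fitted) sprintf("fitted (%d epochs, final loss %.4g)",
                                    length(x$loss_history),
                                    utils::tail(x$loss_history, 1))
              else "untrained",
              format(sum(x$layer_table$params), big.mark = ",")))
  print(x$layer_table, row.names = FALSE)
  invisible(x)
}

# stack a list of equally-sized matrices into an (H, W, n) array, applying
# the model's fixed input scaling
windows_to_array <- function(model, windows) {
  d <- dim(windows[[1]])
  if (!identical(as.integer(d), model$input_shape))
    stop("window shape ", paste(d, collapse = " x "),
         " does not match the model input ",
         paste(model$input_shape, collapse = " x "))
  arr <- array(unlist(windows, use.names = FALSE),
               dim = c(d[1], d[2], length(windows)))
  if (model$kind == "lenet5") {
    arr / 255                       # gaze plots arrive as 0..255
  } else {
    # per-window standardization of the microvolt scale
    for (i in seq_len(dim(arr)[3])) {
      s <- stats::sd(arr[, , i])
      if (s > 0) arr[, , i] <- (arr[, , i] - mean(arr[, , i])) / s
    }
    arr
  }
}

#' Train a deep feature extractor
#'
#' Trains the sigmoid-headed network on binary window labels with Adam.
#' All randomness (shuffling) derives from `cfg$seed`, and the optimizer
#' runs single-threaded, so training is reproducible.
#'
#' @param model a [build_cnn_lstm()] or [build_lenet5()] model.
#' @param windows list of input matrices (EEG windows or gaze plots).
#' @param labels binary vector, one label per window.
#' @param cfg a [training_config()].
#' @return The fitted model (with `loss_history` filled in).
#' @export
train_extractor <- function(model, windows, labels, cfg = training_config()) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class; the loss is degenerate")
  if (length(windows) != length(labels))
    stop("windows and labels must have equal length")
  arr <- windows_to_array(model, windows)
  n <- length(windows)
  set.seed(cfg$seed)
  order_mat <- t(vapply(seq_len(cfg$epochs), function(e) sample.int(n),
                        integer(n)))
  loss_code <- if (cfg$loss == "mse") 0L else 1L
  fn <- if (model$kind == "cnn_lstm") cnnlstm_train_cpp else lenet_train_cpp
  res <- fn(model$weights, arr, labels, order_mat, cfg$batch_size, cfg$lr,
            cfg$beta1, cfg$beta2, cfg$eps, loss_code)
  model$weights <- res$weights
  model$loss_history <- c(model$loss_history, as.numeric(res$loss))
  model$fitted <- TRUE
  model
}

#' Extract deep features from windows
#'
#' A pure function of the model weights and inputs. The default `flatten`
#' layer gives the widths that feature-level fusion concatenates (14,016 for
#' EEG, 2,704 for gaze plots); `last_dense` gives the compact 64- and 84-dim
#' representations used by the desk-scale experiment profile.
#'
#' @param model a (typically fitted) extractor model.
#' @param windows list of input matrices.
#' @param layer `"flatten"` or `"last_dense"`.
#' @return Numeric matrix, one row per window.
#' @export
extract_features <- function(model, windows, layer = c("flatten", "last_dense")) {
  layer <- match.arg(layer)
  arr <- windows_to_array(model, windows)
  code <- if (layer == "flatten") 0L else 1L
  out <- if (model$kind == "cnn_lstm") cnnlstm_features_cpp(model$weights, arr, code)
         else lenet_features_cpp(model$weights, arr, code)
  prefix <- if (model$kind == "cnn_lstm") "eegdeep" else "etdeep"
  colnames(out) <- paste0(prefix, "_", layer, "_", seq_len(ncol(out)))
  out
}
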