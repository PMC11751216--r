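# ---- independent oracles ---------------------------------------------------

# direct-summation statistics (population variance; bias-corrected gamma1/2)
oracle_stats <- function(x) {
  N <- length(x)
  mu <- sum(x) / N
  v <- sum((x - mu)^2) / N
  s <- sqrt(sum((x - mu)^2) / (N - 1))
  z <- (x - mu) / s
  g1 <- N / ((N - 1) * (N - 2)) * sum(z^3)
  g2 <- N * (N + 1) / ((N - 1) * (N - 2) * (N - 3)) * sum(z^4) -
    3 * (N - 1)^2 / ((N - 2) * (N - 3))
  c(mu, v, g1, g2)
}

# Welch PSD by explicit DFT matrices (no fft), same estimator definition
oracle_welch <- function(x, fs = 300, seg_len = 150) {
  hop <- seg_len / 2
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1)))
  k <- 0:(seg_len / 2)
  ang <- -2 * pi * outer(k, 0:(seg_len - 1)) / seg_len
  C <- cos(ang); S <- sin(ang)
  acc <- 0
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1)] * w
    P <- ((C %*% seg)^2 + (S %*% seg)^2) / (fs * sum(w^2))
    P[2:(seg_len / 2)] <- 2 * P[2:(seg_len / 2)]
    acc <- acc + as.numeric(P)
  }
  list(freq = k * fs / seg_len, psd = acc / length(starts))
}

oracle_band_powers <- function(x, fs = 300) {
  est <- oracle_welch(x, fs)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, 45))
  vapply(bands, function(b)
    mean(est$psd[est$freq >= b[1] & est$freq < b[2]]), numeric(1))
}

# DWT by explicit analysis matrices (rows = circularly shifted filters)
oracle_dwt_mats <- function(N, h, g) {
  half <- N / 2
  A <- matrix(0, half, N); D <- matrix(0, half, N)
  for (n in seq_len(half)) {
    for (k in seq_along(h)) {
      j <- ((2 * (n - 1) + (k - 1)) %% N) + 1
      A[n, j] <- A[n, j] + h[k]
      D[n, j] <- D[n, j] + g[k]
    }
  }
  list(A = A, D = D)
}

oracle_dwt_features <- function(x, level = 4) {
  h <- neurochoice:::dwt_filter("db4"); g <- neurochoice:::qmf(h)
  out <- numeric(0)
  a <- x
  for (l in seq_len(level)) {
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    m <- oracle_dwt_mats(length(a), h, g)
    d <- as.numeric(m$D %*% a)
    out <- c(out, mean(d), stats::sd(d))
    a <- as.numeric(m$A %*% a)
  }
  c(out, mean(a), stats::sd(a))
}

# ---- tests -----------------------------------------------------------------

test_that("signal statistics match hand-computed examples", {
  st <- stat_features(c(2, 4, 6, 4))
  expect_equal(unname(st["mean"]), 4)
  expect_equal(unname(st["variance"]), 2)      # divisor N = 4
  # symmetric data have zero skewness
  sym <- stat_features(c(-1, 0, 1, 0, -1, 0, 1, 0))
  expect_equal(unname(sym["skewness"]), 0, tolerance = 1e-12)
  # constant signal: degenerate higher moments, flagged
  cst <- stat_features(rep(5, 10))
  expect_identical(unname(cst[c("skewness", "kurtosis")]), c(0, 0))
  expect_true(attr(cst, "degenerate"))
  expect_error(stat_features(c(1, 2, 3)), "at least 4")
})

test_that("statistics match the direct-summation oracle on random and outlier data", {
  expect_equal(as.numeric(stat_features(c(1, 2, 3, 4, 100))),
               oracle_stats(c(1, 2, 3, 4, 100)), tolerance = 1e-12)
  set.seed(51)
  for (i in 1:200) {
    x <- rnorm(300, sd = runif(1, 0.1, 50))
    expect_equal(as.numeric(stat_features(x)), oracle_stats(x),
                 tolerance = 1e-10)
  }
})

test_that("Welch band powers behave physically and match the DFT oracle", {
  expect_identical(unname(welch_band_powers(rep(0, 300))), rep(0, 5))

  tt <- (0:299) / 300
  bp <- welch_band_powers(sin(2 * pi * 10 * tt))
  expect_true(all(bp["alpha"] >= 20 * bp[c("delta", "theta", "beta", "gamma")]))

  set.seed(52)
  for (i in 1:50) {
    x <- rnorm(300)
    expect_equal(welch_band_powers(x), oracle_band_powers(x),
                 tolerance = 1e-10)
  }
  expect_error(welch_band_powers(rnorm(100)), "shorter than one Welch segment")
})

test_that("white-noise band powers are flat across the PSD", {
  set.seed(53)
  acc <- rowMeans(vapply(1:400, function(i) welch_band_powers(rnorm(300)),
                         numeric(5)))
  # a white PSD is constant, so mean band powers agree within sampling error
  expect_lt(max(acc) / min(acc), 1.15)
})

test_that("DWT features match the matrix-form oracle and analytic cases", {
  expect_true(all(dwt_features(rep(0, 300)) == 0))

  cf <- dwt_features(rep(2, 304))
  expect_lt(max(abs(cf[grep("^d", names(cf))])), 1e-12)
  expect_equal(unname(cf["a4_mean"]), 2 * 2^(4 / 2), tolerance = 1e-10)

  set.seed(54)
  for (i in 1:100) {
    x <- rnorm(300)
    expect_equal(unname(dwt_features(x)), oracle_dwt_features(x),
                 tolerance = 1e-10)
  }
})

test_that("EEG feature vector has the documented fixed width", {
  set.seed(55)
  w <- matrix(rnorm(19 * 300), 19, 300)
  f <- eeg_hand_features(w)
  expect_length(f, 19 * (4 + 5 + 2 * 5))   # 361
  expect_false(anyNA(f))
  # constant width across windows
  expect_length(eeg_hand_features(matrix(rnorm(19 * 300), 19, 300)), 361)
})

test_that("ET features reduce to simple geometry", {
  fx <- data.frame(start_ms = c(0, 300), end_ms = c(250, 600),
                   duration_ms = c(250, 300), x = c(0, 3), y = c(0, 4),
                   n_samples = c(30, 36))
  f <- et_hand_features(fx)
  expect_equal(unname(f["saccade_amp_mean"]), 5)   # 3-4-5 triangle
  expect_equal(unname(f["fix_duration_mean"]), 275)
  expect_equal(unname(f["saccade_count"]), 1)

  f3 <- et_hand_features(data.frame(start_ms = 0, end_ms = 0,
                                    duration_ms = c(100, 100, 100),
                                    x = c(0, 0, 0), y = c(0, 10, 30),
                                    n_samples = 1))
  expect_equal(unname(f3["saccade_amp_mean"]), 15)  # (10 + 20) / 2

  single <- et_hand_features(data.frame(start_ms = 0, end_ms = 250,
                                        duration_ms = 250, x = 1, y = 2,
                                        n_samples = 30))
  expect_equal(unname(single["fix_duration_mean"]), 250)
  expect_equal(unname(single["saccade_amp_mean"]), 0)
  expect_true(attr(single, "degenerate"))

  none <- et_hand_features(detect_fixations(cbind(numeric(0), numeric(0)),
                                            fs = 120))
  expect_true(all(none == 0))
  expect_true(attr(none, "degenerate"))
})
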