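test_that("band-pass respects the 0.5-45 Hz design: passband flat, stopband and DC crushed", {
  fs <- 300; n <- 3000
  tt <- (seq_len(n) - 1) / fs
  mk <- function(x) eeg_recording(matrix(x, 1, n), fs = fs)
  core <- 501:2500   # avoid filter edge transients

  in10 <- sin(2 * pi * 10 * tt)
  out10 <- bandpass(mk(in10))$data[1, ]
  expect_lt(abs(sqrt(mean(out10[core]^2)) / sqrt(mean(in10[core]^2)) - 1), 0.05)

  in100 <- sin(2 * pi * 100 * tt)
  out100 <- bandpass(mk(in100))$data[1, ]
  atten_db <- 20 * log10(sqrt(mean(in100[core]^2)) / sqrt(mean(out100[core]^2)))
  expect_gt(atten_db, 30)

  outdc <- bandpass(mk(rep(1, n)))$data[1, ]
  expect_lt(sqrt(mean(outdc[core]^2)), 0.01)

  expect_error(bandpass(eeg_recording(matrix(0, 1, 100), fs = 80)), "too low")
})

test_that("band-pass is linear", {
  set.seed(31)
  n <- 1500
  x <- rnorm(n); y <- rnorm(n)
  mk <- function(v) eeg_recording(matrix(v, 1, n), fs = 300)
  fx <- bandpass(mk(x))$data[1, ]
  fy <- bandpass(mk(y))$data[1, ]
  fxy <- bandpass(mk(2 * x - 3 * y))$data[1, ]
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))) / max(abs(fxy)), 1e-9)
})

test_that("ASR passes clean data through and removes injected blink transients", {
  set.seed(32)
  fs <- 300; n <- 6000
  clean <- matrix(rnorm(19 * n), 19, n)
  rec <- eeg_recording(clean, fs = fs)
  state <- asr_calibrate(rec, cleaner_config())
  out <- asr_apply(rec, state, cleaner_config())$data
  for (ch in c(1, 10, 19))
    expect_gt(stats::cor(out[ch, ], clean[ch, ]), 0.95)
  expect_lt(mean((out - clean)^2) / mean(clean^2), 0.05)

  # blink: high-amplitude frontal transient on top of the clean signal
  tt <- (seq_len(n) - 1) / fs
  bump <- 300 * exp(-(tt - 10)^2 / (2 * 0.08^2))
  dirty <- clean
  dirty[1:4, ] <- dirty[1:4, ] + rep(bump, each = 4)
  drec <- eeg_recording(dirty, fs = fs)
  dstate <- asr_calibrate(drec, cleaner_config())
  dout <- asr_apply(drec, dstate, cleaner_config())$data
  blink_win <- abs(tt - 10) < 0.15
  expect_lt(max(abs(dout[1, blink_win])), 0.5 * max(abs(dirty[1, blink_win])))
  # quiet intervals barely change
  quiet <- abs(tt - 10) > 1
  rel <- sqrt(mean((dout[1, quiet] - dirty[1, quiet])^2) / mean(dirty[1, quiet]^2))
  expect_lt(rel, 0.10)
})

test_that("ASR edge cases: infinite thresholds give identity; rank deficiency is tolerated", {
  set.seed(33)
  rec <- eeg_recording(matrix(rnorm(19 * 3000), 19, 3000), fs = 300)
  state <- asr_calibrate(rec, cleaner_config())
  state$thresholds[] <- Inf
  out <- asr_apply(rec, state, cleaner_config())$data
  expect_lt(max(abs(out - rec$data)) / max(abs(rec$data)), 1e-6)

  # two perfectly correlated channels: covariance is rank-deficient
  X <- matrix(rnorm(5 * 3000), 5, 3000)
  X[2, ] <- X[1, ]
  expect_no_error(state2 <- asr_calibrate(eeg_recording(X, fs = 300),
                                          cleaner_config()))
  expect_true(all(is.finite(state2$thresholds)))
})

test_that("ASR calibration flags a window containing a large transient", {
  set.seed(34)
  fs <- 300
  clean <- matrix(rnorm(19 * 6000), 19, 6000)
  rec <- eeg_recording(clean, fs = fs)
  state <- asr_calibrate(rec, cleaner_config())
  blink <- clean[, 1:150]
  blink[1, ] <- blink[1, ] + 300 * exp(-((1:150) - 75)^2 / (2 * 24^2))
  Y <- t(state$V) %*% blink
  expect_true(any(sqrt(rowMeans(Y^2)) > state$thresholds))
})

test_that("wavelet cleaner suppresses spikes but keeps oscillations", {
  cfg <- cleaner_config()
  expect_identical(force_clean(matrix(0, 19, 300), cfg), matrix(0, 19, 300))

  set.seed(35)
  tt <- (0:299) / 300
  sine <- sin(2 * pi * 10 * tt)
  W <- matrix(rep(sine, 19), 19, byrow = TRUE) + matrix(rnorm(19 * 300, 0, 0.05), 19)
  out <- force_clean(W, cfg)
  expect_identical(dim(out), dim(W))
  for (ch in c(1, 9, 19)) expect_gt(stats::cor(out[ch, ], W[ch, ]), 0.9)

  spiked <- W
  spiked[5, 150] <- spiked[5, 150] + 500
  outs <- force_clean(spiked, cfg)
  spike_excess <- abs(outs[5, 150] - sine[150])
  expect_lt(spike_excess, 0.2 * 500)            # >= 80% of the spike removed
  rms_ratio <- sqrt(mean(outs[5, -(140:160)]^2) / mean(W[5, -(140:160)]^2))
  expect_gt(rms_ratio, 0.8); expect_lt(rms_ratio, 1.2)

  expect_error(force_clean(matrix(0, 2, 8), cfg), "incompatible")
})

test_that("segmentation follows the 1-s / 50%-overlap hop rule exactly", {
  mkrec <- function(L) eeg_recording(matrix(seq_len(19 * L), 19, L), fs = 300,
                                     trials = trial_annotation(0, L, 1))
  expect_length(segment(mkrec(300))$windows, 1)
  s600 <- segment(mkrec(600))
  expect_length(s600$windows, 3)
  expect_identical(s600$info$start, c(0L, 150L, 300L))
  expect_length(segment(mkrec(1200))$windows, 7)

  # windowing is a pure view: window contents equal the original slices
  rec <- mkrec(600)
  for (k in 1:3) {
    st <- s600$info$start[k]
    expect_identical(s600$windows[[k]], rec$data[, (st + 1):(st + 300)])
  }
  # labels and subject metadata are inherited
  expect_true(all(s600$info$label == 1L))

  short <- eeg_recording(matrix(0, 19, 400), fs = 300,
                         trials = rbind(trial_annotation(0, 100, 1),
                                        trial_annotation(100, 400, 0)))
  expect_warning(sw <- segment(short), "shorter than one window")
  expect_length(sw$windows, 1)
})

test_that("the full cleaning chain preserves shape and channel order", {
  cfg <- tiny_strong_cfg(seed = 6)
  rec <- generate_recordings(cfg)[[1]]$eeg
  ws <- preprocess_eeg(rec)
  expect_true(all(vapply(ws$windows, function(w)
    identical(dim(w), c(19L, 300L)), logical(1))))
  expect_identical(nrow(ws$info), length(ws$windows))
})
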