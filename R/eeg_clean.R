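#' Configuration for the EEG cleaning chain
#'
#' The chain is: zero-phase Butterworth band-pass (0.5-45 Hz), Artifact
#' Subspace Reconstruction on the continuous recording, segmentation into 1-s
#' windows with 50% overlap, and per-window wavelet-threshold transient
#' suppression ("FORCe-style" cleaning).
#'
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param filter_order Butterworth order for each of the high-pass and
#'   low-pass stages (applied forward-backward, so the effective attenuation
#'   is doubled).
#' @param asr_cutoff rejection threshold in calibration standard deviations.
#' @param asr_window sliding-window length in seconds.
#' @param asr_calibration_fraction fraction of the cleanest windows (lowest
#'   robust RMS) used to calibrate the subspace model.
#' @param force_wavelet,force_level wavelet family and decomposition depth of
#'   the per-window cleaner.
#' @param force_threshold_k robust threshold multiplier: detail coefficients
#'   exceeding `k * median(|d|) / 0.6745` are zeroed per level, and a channel's
#'   approximation band is zeroed when its energy exceeds `k` times the
#'   across-channel median.
#' @param window_s,overlap segmentation window length (s) and overlap
#'   fraction.
#' @return A list of class `cleaner_config`.
#' @export
cleaner_config <- function(band = c(0.5, 45), filter_order = 4,
                           asr_cutoff = 20, asr_window = 0.5,
                           asr_calibration_fraction = 0.25,
                           force_wavelet = "db4", force_level = 4,
                           force_threshold_k = 3,
                           window_s = 1, overlap = 0.5) {
  if (band[1] <= 0 || band[1] >= band[2]) stop("band must satisfy 0 < low < high")
  if (overlap <= 0 || overlap >= 1) stop("overlap must be in (0, 1)")
  if (asr_cutoff <= 0) stop("asr_cutoff must be positive")
  structure(list(band = band, filter_order = filter_order,
                 asr_cutoff = asr_cutoff, asr_window = asr_window,
                 asr_calibration_fraction = asr_calibration_fraction,
                 force_wavelet = force_wavelet, force_level = force_level,
                 force_threshold_k = force_threshold_k,
                 window_s = window_s, overlap = overlap),
            class = "cleaner_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applied per channel as a cascade of an order-`filter_order` Butterworth
#' high-pass at `band[1]` and low-pass at `band[2]`, each factored into
#' second-order sections (the 0.5 Hz edge at 300 Hz makes a single
#' polynomial realization numerically fragile) and run forward-backward
#' ([signal::filtfilt()]) so the net phase response is zero.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [cleaner_config()].
#' @return The filtered `eeg_recording` (same shape).
#' @export
bandpass <- function(rec, cfg = cleaner_config()) {
  fs <- rec$fs
  if (fs <= 2 * cfg$band[2])
    stop("sampling rate ", fs, " Hz is too low for a band edge at ",
         cfg$band[2], " Hz")
  secs <- c(butter_sos(cfg$filter_order, cfg$band[1], fs, "high"),
            butter_sos(cfg$filter_order, cfg$band[2], fs, "low"))
  out <- t(apply(rec$data, 1, function(x) {
    for (s in secs) x <- signal::filtfilt(s, x)
    x
  }))
  rec$data <- out
  rec
}

# Butterworth filter of even order n as second-order sections (bilinear
# transform with frequency prewarp; section Q = 1 / (2 cos(theta_k)))
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (n %% 2 != 0) stop("filter_order must be even")
  K <- tan(pi * fc / fs)
  lapply(seq_len(n / 2), function(k) {
    Q <- 1 / (2 * cos(pi * (2 * k - 1) / (2 * n)))
    norm <- 1 / (1 + K / Q + K * K)
    b <- if (type == "low") c(K * K, 2 * K * K, K * K) * norm
         else c(1, -2, 1) * norm
    a <- c(1, 2 * (K * K - 1) * norm, (1 - K / Q + K * K) * norm)
    signal::Arma(b = b, a = a)
  })
}

#' Calibrate an Artifact Subspace Reconstruction model
#'
#' Slides `asr_window`-second windows (50% overlap) over the band-passed
#' recording, ranks them by their worst-channel RMS (so a transient confined
#' to a few channels still disqualifies a window), and keeps the cleanest
#' `asr_calibration_fraction` as calibration data. The model is the PCA basis of the calibration covariance (with an
#' eigenvalue floor against rank deficiency) plus per-component rejection
#' thresholds `mean + asr_cutoff * SD` of the calibration component RMS.
#'
#' @param rec a band-passed `eeg_recording`.
#' @param cfg a [cleaner_config()].
#' @return A list of class `asr_state` with the PCA basis `V`, per-component
#'   `thresholds`, window length `w` and the channel count.
#' @export
asr_calibrate <- function(rec, cfg = cleaner_config()) {
  X <- rec$data
  w <- round(cfg$asr_window * rec$fs)
  if (ncol(X) < w)
    stop("recording (", ncol(X), " samples) is shorter than one ASR window (",
         w, " samples)")
  starts <- window_starts(ncol(X), w, w %/% 2)
  # rank windows by their worst channel: a transient confined to a few
  # channels must still disqualify the window from calibration
  rms <- vapply(starts, function(s) {
    seg <- X[, s:(s + w - 1), drop = FALSE]
    max(sqrt(rowMeans(seg^2)))
  }, numeric(1))
  n_cal <- max(2L, ceiling(cfg$asr_calibration_fraction * length(starts)))
  cal_starts <- starts[order(rms)[seq_len(n_cal)]]
  cal_idx <- unique(unlist(lapply(cal_starts, function(s) s:(s + w - 1))))
  Xcal <- X[, cal_idx, drop = FALSE]
  C <- stats::cov(t(Xcal))
  eg <- eigen(C, symmetric = TRUE)
  floor_val <- 1e-12 * sum(diag(C))
  eg$values <- pmax(eg$values, floor_val)
  V <- eg$vectors
  comp_rms <- vapply(cal_starts, function(s) {
    Y <- t(V) %*% X[, s:(s + w - 1), drop = FALSE]
    sqrt(rowMeans(Y^2))
  }, numeric(nrow(X)))
  thr <- rowMeans(comp_rms) + cfg$asr_cutoff * apply(comp_rms, 1, stats::sd)
  structure(list(V = V, thresholds = thr, w = w,
                 n_channels = nrow(X), channel_names = rec$channel_names),
            class = "asr_state")
}

#' Apply a calibrated ASR model
#'
#' Slides windows (50% overlap, Hann-tapered overlap-add) over the recording;
#' in each window the data are projected onto the calibration PCA basis,
#' components whose RMS exceeds their threshold are zeroed, and the window is
#' reconstructed. With no component above threshold the reconstruction is the
#' identity, so clean data pass through (numerically) untouched.
#'
#' @param rec a band-passed `eeg_recording`.
#' @param state an [asr_calibrate()] result for the same channel set.
#' @param cfg a [cleaner_config()].
#' @return The reconstructed `eeg_recording` (same shape).
#' @export
asr_apply <- function(rec, state, cfg = cleaner_config()) {
  if (!inherits(state, "asr_state") || state$n_channels != nrow(rec$data))
    stop("ASR state does not match the recording's channel set")
  X <- rec$data
  n <- ncol(X); w <- state$w
  hop <- w %/% 2
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
  acc <- matrix(0, nrow(X), n)
  wacc <- numeric(n)
  starts <- window_starts(n, w, hop)
  for (s in starts) {
    idx <- s:(s + w - 1)
    Y <- t(state$V) %*% X[, idx, drop = FALSE]
    bad <- sqrt(rowMeans(Y^2)) > state$thresholds
    if (any(bad)) Y[bad, ] <- 0
    rebuilt <- state$V %*% Y
    acc[, idx] <- acc[, idx] + rebuilt * rep(taper, each = nrow(X))
    wacc[idx] <- wacc[idx] + taper
  }
  covered <- wacc > 1e-12
  out <- X
  out[, covered] <- acc[, covered] / rep(wacc[covered], each = nrow(X))
  rec$data <- out
  rec
}

window_starts <- function(n, w, hop) {
  starts <- seq(1L, max(n - w + 1L, 1L), by = hop)
  # make sure the tail is covered
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)
  starts
}

#' Wavelet-threshold transient suppression for one EEG window
#'
#' A FORCe-style per-window cleaner. Each channel is decomposed with a
#' periodized DWT; detail coefficients exceeding the robust per-level
#' threshold `k * median(|d|) / 0.6745` are zeroed (coefficients below the
#' threshold — the bulk of any band-limited physiological rhythm — pass
#' untouched, while transient outliers are rejected outright, mirroring how
#' ASR drops whole components). In channels whose approximation energy
#' exceeds `k` times the across-channel median, approximation coefficients
#' deviating grossly from the cross-channel ensemble at their position are
#' zeroed as well (suppressing large low-frequency transients such as blinks
#' without deleting shared slow activity), before inverse transformation.
#'
#' @param window numeric channels x samples matrix (one segmentation window).
#' @param cfg a [cleaner_config()].
#' @return The cleaned matrix, same shape.
#' @export
force_clean <- function(window, cfg = cleaner_config()) {
  if (ncol(window) < 2^cfg$force_level)
    stop("window of ", ncol(window), " samples is incompatible with a depth-",
         cfg$force_level, " decomposition")
  k <- cfg$force_threshold_k
  decs <- lapply(seq_len(nrow(window)), function(ch)
    nc_dwt(window[ch, ], level = cfg$force_level, wavelet = cfg$force_wavelet))
  approx_energy <- vapply(decs, function(d) sum(d$approx^2), numeric(1))
  kill_approx <- approx_energy > k * stats::median(approx_energy)
  # per-position robust scale of the approximation across channels
  A <- do.call(rbind, lapply(decs, `[[`, "approx"))
  a_scale <- apply(abs(A), 2, stats::median) / 0.6745
  out <- window
  for (ch in seq_len(nrow(window))) {
    d <- decs[[ch]]
    d$details <- lapply(d$details, function(dd) {
      t <- k * stats::median(abs(dd)) / 0.6745
      dd[abs(dd) > t] <- 0
      dd
    })
    if (kill_approx[ch]) {
      bad <- abs(d$approx) > k * a_scale
      d$approx[bad] <- 0
    }
    out[ch, ] <- nc_idwt(d)
  }
  out
}

#' Segment a recording's trials into overlapping windows
#'
#' Pure windowing (no filtering): per trial, windows of
#' `window_s * fs` samples with a hop of `(1 - overlap) * window_s * fs`
#' samples, each inheriting the trial's label and the subject id. A trial
#' yields `floor((L - w) / hop) + 1` windows; trials shorter than one window
#' yield none (with a warning).
#'
#' @param rec an `eeg_recording` with trial annotations.
#' @param cfg a [cleaner_config()] (or [gaze_config()] for ET use).
#' @return An object of class `nc_windows`: list with `windows` (list of
#'   channels x samples matrices) and `info` (data frame with `subject`,
#'   `trial`, `ordinal`, `start`, `label`).
#' @export
segment <- function(rec, cfg = cleaner_config()) {
  w <- round(cfg$window_s * rec$fs)
  hop <- round(w * (1 - cfg$overlap))
  if (!nrow(rec$trials)) stop("recording has no trial annotations")
  windows <- list(); info <- list()
  for (tr in seq_len(nrow(rec$trials))) {
    t0 <- rec$trials$start[tr]; t1 <- rec$trials$end[tr]
    L <- t1 - t0
    if (L < w) {
      warning("trial ", tr, " (", L, " samples) is shorter than one window; skipped")
      next
    }
    starts <- as.integer(seq(t0, t1 - w, by = hop))
    for (oi in seq_along(starts)) {
      idx <- (starts[oi] + 1L):(starts[oi] + w)
      windows[[length(windows) + 1L]] <-
        if (inherits(rec, "eeg_recording")) rec$data[, idx, drop = FALSE]
        else cbind(x = rec$gaze_x[idx], y = rec$gaze_y[idx])
      info[[length(info) + 1L]] <-
        data.frame(subject = rec$subject_id, trial = tr, ordinal = oi,
                   start = starts[oi], label = rec$trials$label[tr],
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(windows = windows, info = do.call(rbind, info)),
            class = "nc_windows")
}

#' @export
print.nc_windows <- function(x, ...) {
  n <- length(x$windows)
  cat(sprintf("<nc_windows> %d windows (%s) from %d trials, %d subjects\n", n,
              if (n) paste(dim(x$windows[[1]]), collapse = "x") else "-",
              if (n) length(unique(paste(x$info$subject, x$info$trial))) else 0,
              if (n) length(unique(x$info$subject)) else 0))
  invisible(x)
}

#' Full EEG preprocessing chain
#'
#' Band-pass filter, optional ASR on the continuous recording, segmentation,
#' and optional per-window wavelet cleaning. The skip switches reproduce the
#' "not preprocessed" ablation configurations.
#'
#' @param rec an `eeg_recording` with trials.
#' @param cfg a [cleaner_config()].
#' @param asr,force logical switches for the two artifact-removal stages.
#' @return An `nc_windows` object of cleaned windows.
#' @export
preprocess_eeg <- function(rec, cfg = cleaner_config(), asr = TRUE, force = TRUE) {
  rec <- bandpass(rec, cfg)
  if (asr) {
    state <- asr_calibrate(rec, cfg)
    rec <- asr_apply(rec, state, cfg)
  }
  ws <- segment(rec, cfg)
  if (force) ws$windows <- lapply(ws$windows, force_clean, cfg = cfg)
  ws
}
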