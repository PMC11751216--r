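#' Time-domain statistics of a signal
#'
#' Mean, population variance (divisor N), and bias-corrected skewness and
#' excess kurtosis:
#' \deqn{\gamma_1 = \frac{N}{(N-1)(N-2)} \sum \left(\frac{x_i - \mu}{s}\right)^3}
#' \deqn{\gamma_2 = \frac{N(N+1)}{(N-1)(N-2)(N-3)} \sum \left(\frac{x_i - \mu}{s}\right)^4
#'   - \frac{3(N-1)^2}{(N-2)(N-3)}}
#' with `s` the sample standard deviation (divisor N-1). The variance
#' deliberately uses divisor N while the higher moments use the corrected
#' forms; the mix is kept as-is and documented.
#'
#' @param x numeric vector, length >= 4.
#' @return Named vector `c(mean, variance, skewness, kurtosis)`. For a
#'   constant signal the higher moments are 0 and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
stat_features <- function(x) {
  N <- length(x)
  if (N < 4) stop("need at least 4 samples for the kurtosis correction")
  mu <- mean(x)
  v <- mean((x - mu)^2)        # population variance, divisor N
  s <- stats::sd(x)            # sample SD used inside the standardization
  degenerate <- s == 0
  if (degenerate) {
    g1 <- 0; g2 <- 0
  } else {
    z <- (x - mu) / s
    g1 <- N / ((N - 1) * (N - 2)) * sum(z^3)
    g2 <- N * (N + 1) / ((N - 1) * (N - 2) * (N - 3)) * sum(z^4) -
      3 * (N - 1)^2 / ((N - 2) * (N - 3))
  }
  out <- c(mean = mu, variance = v, skewness = g1, kurtosis = g2)
  attr(out, "degenerate") <- degenerate
  out
}

#' Frequency band definitions (Hz)
#'
#' Conventional clinical bands truncated at the 45 Hz filter edge. Bands are
#' half-open `[low, high)`.
#' @return Named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' Welch power spectral density estimate
#'
#' Averaged periodograms of Hann-windowed overlapping segments. With the
#' defaults (150-sample segments, 50% overlap) a 300-sample window yields 3
#' segments and a 2 Hz frequency grid.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples.
#' @param overlap segment overlap fraction.
#' @return List with `freq` (Hz) and `psd` (one-sided density).
#' @export
welch_psd <- function(x, fs = 300, seg_len = 150, overlap = 0.5) {
  if (length(x) < seg_len)
    stop("signal (", length(x), " samples) shorter than one Welch segment (",
         seg_len, ")")
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1)))
  U <- sum(w^2)
  nfreq <- seg_len %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    P <- abs(stats::fft(seg))^2 / (fs * U)
    half <- P[seq_len(nfreq)]
    if (nfreq > 2) half[2:(nfreq - 1)] <- 2 * half[2:(nfreq - 1)]
    acc <- acc + half
  }
  list(freq = (seq_len(nfreq) - 1) * fs / seg_len, psd = acc / length(starts))
}

#' Mean Welch band power in the five clinical bands
#'
#' @inheritParams welch_psd
#' @param bands band definition list as from [eeg_bands()].
#' @return Named vector of mean PSD per band (delta, theta, alpha, beta,
#'   gamma).
#' @export
welch_band_powers <- function(x, fs = 300, seg_len = 150, overlap = 0.5,
                              bands = eeg_bands()) {
  est <- welch_psd(x, fs, seg_len, overlap)
  if (max(est$freq) < max(vapply(bands, max, numeric(1))))
    stop("sampling rate too low for the configured band grid")
  vapply(bands, function(b) {
    sel <- est$freq >= b[1] & est$freq < b[2]
    if (!any(sel)) return(0)
    mean(est$psd[sel])
  }, numeric(1))
}

#' Per-level DWT coefficient statistics
#'
#' Mean and standard deviation of the detail coefficients at each level and
#' of the final approximation, using the periodized transform of [nc_dwt()].
#'
#' @param x numeric signal.
#' @param level decomposition depth.
#' @param wavelet wavelet family.
#' @return Named vector `d1_mean, d1_sd, ..., a<level>_mean, a<level>_sd`
#'   (length `2 * (level + 1)`).
#' @export
dwt_features <- function(x, level = 4, wavelet = "db4") {
  dec <- nc_dwt(x, level = level, wavelet = wavelet)
  vals <- c(lapply(dec$details, function(d) c(mean(d), stats::sd(d))),
            list(c(mean(dec$approx), stats::sd(dec$approx))))
  out <- unlist(vals)
  names(out) <- c(paste0(rep(paste0("d", seq_len(level)), each = 2),
                         c("_mean", "_sd")),
                  paste0("a", level, c("_mean", "_sd")))
  out
}

#' Handcrafted EEG features for one window
#'
#' Per channel: the four time-domain statistics, five Welch band powers and
#' `2 * (level + 1)` DWT coefficient statistics — 19 values per channel with
#' the defaults, 361 for 19 channels.
#'
#' @param window channels x samples matrix.
#' @param fs sampling rate.
#' @param dwt_level DWT depth.
#' @param wavelet wavelet family.
#' @return Named feature vector of fixed length
#'   `n_channels * (4 + 5 + 2*(dwt_level+1))`.
#' @export
eeg_hand_features <- function(window, fs = 300, dwt_level = 4, wavelet = "db4") {
  per_ch <- lapply(seq_len(nrow(window)), function(ch) {
    x <- window[ch, ]
    st <- stat_features(x)
    bp <- welch_band_powers(x, fs = fs)
    dw <- dwt_features(x, level = dwt_level, wavelet = wavelet)
    v <- c(st, bp, dw)
    names(v) <- paste0("eeg_ch", ch, "_", c(names(st), names(bp), names(dw)))
    v
  })
  unlist(per_ch)
}

#' Handcrafted ET features from detected fixations
#'
#' Mean fixation duration (ms), fixation count, mean saccade amplitude
#' (Euclidean distance between consecutive fixation centroids, px) and
#' saccade count. With no fixations all features are 0 and the result
#' carries `attr(, "degenerate") = TRUE`.
#'
#' @param fixations a [detect_fixations()] data frame (time-ordered).
#' @return Named vector
#'   `c(fix_duration_mean, fix_count, saccade_amp_mean, saccade_count)`.
#' @export
et_hand_features <- function(fixations) {
  nf <- nrow(fixations)
  if (nf == 0) {
    out <- c(fix_duration_mean = 0, fix_count = 0,
             saccade_amp_mean = 0, saccade_count = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  amp <- if (nf >= 2) {
    dx <- diff(fixations$x); dy <- diff(fixations$y)
    mean(sqrt(dx^2 + dy^2))
  } else 0
  out <- c(fix_duration_mean = mean(fixations$duration_ms), fix_count = nf,
           saccade_amp_mean = amp, saccade_count = max(nf - 1, 0))
  attr(out, "degenerate") <- nf < 2
  out
}
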