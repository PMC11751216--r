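#' Configuration for the synthetic multimodal generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' per-trial EEG segments whose 8-13 Hz (alpha) amplitude is modulated by the
#' buy/no-buy label, gaze scanpaths whose fixation durations and saccade
#' amplitudes shift with the label, and artifacts (blinks, 50 Hz line noise,
#' muscle bursts). Blink gaps in the gaze stream and blink transients in the
#' frontal EEG channels are time-locked, so cross-modal artifact removal has
#' something realistic to work on.
#'
#' @param n_subjects number of synthetic subjects.
#' @param trials_per_subject product-viewing trials per subject.
#' @param buy_fraction target fraction of buy trials per subject; labels are
#'   assigned by exact-count sampling (`round(buy_fraction * trials)`),
#'   clamped so both classes are always present.
#' @param eeg_fs,et_fs sampling rates in Hz.
#' @param n_channels EEG channel count.
#' @param trial_duration trial length in seconds (>= 1).
#' @param class_effect list with `alpha_power_ratio` (multiplier on 8-13 Hz
#'   amplitude in buy trials), `fixation_duration_shift` (ms added to the mean
#'   fixation duration in buy trials) and `saccade_amplitude_shift` (px added
#'   to the mean saccade amplitude in buy trials).
#' @param artifact_rates list with `blinks_per_minute`, `line_noise_amplitude`
#'   (microvolts of 50 Hz interference) and `muscle_burst_rate` (bursts per
#'   minute).
#' @param screen_size screen size in pixels, `c(width, height)`.
#' @param seed master seed; every trial derives its own substream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4, trials_per_subject = 20,
                         buy_fraction = 0.125,
                         eeg_fs = 300, et_fs = 120, n_channels = 19,
                         trial_duration = 3,
                         class_effect = list(alpha_power_ratio = 0.5,
                                             fixation_duration_shift = 200,
                                             saccade_amplitude_shift = 50),
                         artifact_rates = list(blinks_per_minute = 10,
                                               line_noise_amplitude = 2,
                                               muscle_burst_rate = 2),
                         screen_size = c(1920, 1080), seed = 42) {
  cfg <- list(n_subjects = n_subjects, trials_per_subject = trials_per_subject,
              buy_fraction = buy_fraction, eeg_fs = eeg_fs, et_fs = et_fs,
              n_channels = n_channels, trial_duration = trial_duration,
              class_effect = class_effect, artifact_rates = artifact_rates,
              screen_size = screen_size, seed = seed)
  if (buy_fraction <= 0 || buy_fraction >= 1) stop("buy_fraction must be in (0, 1)")
  if (trial_duration < 1) stop("trial_duration must be >= 1 s")
  if (any(unlist(artifact_rates) < 0)) stop("artifact rates must be >= 0")
  if (any(unlist(class_effect) < 0)) stop("class effects must be >= 0")
  structure(cfg, class = "synth_config")
}

#' Strong-effect and null study presets
#'
#' `synth_config_strong()` is the balanced strong-effect condition used by the
#' package's end-to-end experiments (alpha amplitude halved in buy trials,
#' fixation durations 200 ms longer, 400 windows when segmented at 1 s with
#' 50% overlap); `synth_config_null()` is the matched no-signal control.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_strong <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_subjects = 4, trials_per_subject = 20, buy_fraction = 0.5,
         class_effect = list(alpha_power_ratio = 0.5,
                             fixation_duration_shift = 200,
                             saccade_amplitude_shift = 50),
         seed = seed),
    list(...))
  do.call(synth_config, args)
}

#' @rdname synth_config_strong
#' @export
synth_config_null <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_subjects = 4, trials_per_subject = 20, buy_fraction = 0.5,
         class_effect = list(alpha_power_ratio = 1,
                             fixation_duration_shift = 0,
                             saccade_amplitude_shift = 0),
         seed = seed),
    list(...))
  do.call(synth_config, args)
}

# deterministic per-(subject, trial) substream seed below 2^31
trial_seed <- function(cfg, subject, trial, salt = 0) {
  as.integer((as.numeric(cfg$seed) * 1000003 + subject * 10007 +
                trial * 101 + salt) %% 2147483647)
}

#' Generate one synthetic EEG trial
#'
#' Channels are built by spectral synthesis: complex Gaussian spectra shaped
#' by a 1/sqrt(f) envelope restricted to 0.5-45 Hz, with the 8-13 Hz
#' amplitude multiplied by `class_effect$alpha_power_ratio` in buy trials.
#' Artifacts are then injected: 50 Hz line noise common to all channels,
#' frontally-weighted low-frequency blink transients at `blink_times`, and
#' short high-frequency muscle bursts on random channel subsets.
#'
#' @param cfg a [synth_config()].
#' @param label 1 = buy, 0 = no-buy.
#' @param seed integer substream seed (defaults to a stream derived from
#'   `cfg$seed`).
#' @param blink_times blink event times in seconds within the trial; by
#'   default drawn as a Poisson process at `artifact_rates$blinks_per_minute`.
#' @return An `eeg_recording` containing the single annotated trial.
#' @export
generate_eeg_trial <- function(cfg, label, seed = trial_seed(cfg, 1, 1),
                               blink_times = NULL) {
  set.seed(seed)
  n <- round(cfg$trial_duration * cfg$eeg_fs)
  fs <- cfg$eeg_fs
  if (is.null(blink_times)) blink_times <- draw_blink_times(cfg)
  freqs <- seq_len(n %/% 2 - 1) * fs / n
  amp <- ifelse(freqs >= 0.5 & freqs <= 45, 1 / sqrt(freqs), 0)
  if (label == 1) {
    idx <- freqs >= 8 & freqs <= 13
    amp[idx] <- amp[idx] * cfg$class_effect$alpha_power_ratio
  }
  # fixed normalization (target ~10 uV RMS for a neutral trial) so the class
  # effect is not renormalized away: Var(x_t) = 2 * scale^2 * sum(amp^2)
  amp_ref <- ifelse(freqs >= 0.5 & freqs <= 45, 1 / sqrt(freqs), 0)
  scale <- 10 / sqrt(2 * sum(amp_ref^2))
  X <- matrix(0, cfg$n_channels, n)
  tt <- (seq_len(n) - 1) / fs
  for (ch in seq_len(cfg$n_channels)) {
    z <- complex(real = stats::rnorm(length(freqs)),
                 imaginary = stats::rnorm(length(freqs))) / sqrt(2)
    spec <- complex(length.out = n)
    spec[2:(n %/% 2)] <- amp * z * scale
    spec[n:(n %/% 2 + 2)] <- Conj(spec[2:(n %/% 2)])
    X[ch, ] <- Re(stats::fft(spec, inverse = TRUE))
  }
  # 50 Hz line noise, common phase across channels
  if (cfg$artifact_rates$line_noise_amplitude > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    X <- X + matrix(cfg$artifact_rates$line_noise_amplitude *
                      sin(2 * pi * 50 * tt + phi),
                    cfg$n_channels, n, byrow = TRUE)
  }
  # blink transients: smooth high-amplitude frontal bumps (~0.5-2 Hz content)
  frontal_w <- c(1, 0.9, 0.9, 0.6, rep(0.15, max(cfg$n_channels - 4, 0)))[seq_len(cfg$n_channels)]
  for (tb in blink_times) {
    bump <- 150 * exp(-(tt - tb)^2 / (2 * 0.08^2))
    X <- X + outer(frontal_w, bump)
  }
  # muscle bursts: 200 ms hann-enveloped wideband noise on a channel subset
  n_bursts <- stats::rpois(1, cfg$artifact_rates$muscle_burst_rate *
                                cfg$trial_duration / 60)
  for (b in seq_len(n_bursts)) {
    t0 <- stats::runif(1, 0, cfg$trial_duration - 0.2)
    i0 <- floor(t0 * fs) + 1
    len <- round(0.2 * fs)
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    chans <- sample(cfg$n_channels, 3)
    for (ch in chans)
      X[ch, i0:(i0 + len - 1)] <- X[ch, i0:(i0 + len - 1)] +
        20 * env * stats::rnorm(len)
  }
  eeg_recording(X, fs = fs, subject_id = "synth",
                trials = trial_annotation(0L, n, label))
}

draw_blink_times <- function(cfg) {
  n_blinks <- stats::rpois(1, cfg$artifact_rates$blinks_per_minute *
                                cfg$trial_duration / 60)
  sort(stats::runif(n_blinks, 0.3, cfg$trial_duration - 0.3))
}

#' Generate one synthetic eye-tracking trial
#'
#' The scanpath alternates fixations (lognormal durations whose mean is
#' shifted by `class_effect$fixation_duration_shift` in buy trials; gaze =
#' centre + small jitter) with short ballistic saccades whose amplitudes are
#' gamma-distributed with a class-shifted mean. Blink gaps are inserted as
#' runs of `valid = FALSE` (coordinates missing) at `blink_times`.
#'
#' @inheritParams generate_eeg_trial
#' @return An `et_recording` containing the single annotated trial.
#' @export
generate_et_trial <- function(cfg, label, seed = trial_seed(cfg, 1, 1, salt = 7),
                              blink_times = NULL) {
  set.seed(seed)
  fs <- cfg$et_fs
  n <- round(cfg$trial_duration * fs)
  if (is.null(blink_times)) blink_times <- draw_blink_times(cfg)
  W <- cfg$screen_size[1]; H <- cfg$screen_size[2]
  mean_fix <- 250 + label * cfg$class_effect$fixation_duration_shift   # ms
  mean_sacc <- 150 + label * cfg$class_effect$saccade_amplitude_shift  # px
  sdlog <- 0.35
  x <- numeric(n); y <- numeric(n)
  cx <- stats::runif(1, 0.3 * W, 0.7 * W)
  cy <- stats::runif(1, 0.3 * H, 0.7 * H)
  i <- 1L
  while (i <= n) {
    dur_ms <- stats::rlnorm(1, log(mean_fix) - sdlog^2 / 2, sdlog)
    len <- max(2L, round(dur_ms / 1000 * fs))
    j <- min(n, i + len - 1L)
    x[i:j] <- cx + stats::rnorm(j - i + 1, 0, 2)
    y[i:j] <- cy + stats::rnorm(j - i + 1, 0, 2)
    i <- j + 1L
    if (i > n) break
    # ballistic saccade to the next fixation centre (~33 ms)
    amp <- stats::rgamma(1, shape = 4, scale = mean_sacc / 4)
    theta <- stats::runif(1, 0, 2 * pi)
    nx <- min(max(cx + amp * cos(theta), 0.05 * W), 0.95 * W)
    ny <- min(max(cy + amp * sin(theta), 0.05 * H), 0.95 * H)
    slen <- min(max(2L, round(0.033 * fs)), n - i + 1L)
    x[i:(i + slen - 1L)] <- seq(cx, nx, length.out = slen + 2)[2:(slen + 1)]
    y[i:(i + slen - 1L)] <- seq(cy, ny, length.out = slen + 2)[2:(slen + 1)]
    cx <- nx; cy <- ny
    i <- i + slen
  }
  x <- pmin(pmax(x, 0), W - 1e-9)
  y <- pmin(pmax(y, 0), H - 1e-9)
  valid <- rep(TRUE, n)
  for (tb in blink_times) {
    gap_ms <- stats::runif(1, 100, 250)
    i0 <- max(1L, floor(tb * fs) + 1L)
    i1 <- min(n, i0 + round(gap_ms / 1000 * fs) - 1L)
    valid[i0:i1] <- FALSE
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  et_recording(x, y, valid, fs = fs, screen_size = cfg$screen_size,
               subject_id = "synth", trials = trial_annotation(0L, n, label))
}

# exact-count label assignment; both classes guaranteed
assign_labels <- function(cfg, subject) {
  set.seed(trial_seed(cfg, subject, 0, salt = 3))
  tps <- cfg$trials_per_subject
  n_buy <- min(max(round(cfg$buy_fraction * tps), 1L), tps - 1L)
  labels <- integer(tps)
  labels[sample(tps, n_buy)] <- 1L
  labels
}

#' Generate paired EEG + ET recordings for all subjects in memory
#'
#' Trials are laid back-to-back within each subject's continuous recording;
#' the EEG and ET streams share trial boundaries (in seconds) and blink event
#' times, so the two modalities are temporally aligned.
#'
#' @param cfg a [synth_config()].
#' @return A list with one element per subject, each a list with `eeg`
#'   (`eeg_recording`) and `et` (`et_recording`).
#' @export
generate_recordings <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(s) {
    labels <- assign_labels(cfg, s)
    eeg_parts <- list(); et_parts <- list()
    for (tr in seq_along(labels)) {
      set.seed(trial_seed(cfg, s, tr, salt = 5))
      bt <- draw_blink_times(cfg)
      eeg_parts[[tr]] <- generate_eeg_trial(cfg, labels[tr],
                                            seed = trial_seed(cfg, s, tr),
                                            blink_times = bt)
      et_parts[[tr]] <- generate_et_trial(cfg, labels[tr],
                                          seed = trial_seed(cfg, s, tr, salt = 7),
                                          blink_times = bt)
    }
    sid <- sprintf("S%02d", s)
    ne <- round(cfg$trial_duration * cfg$eeg_fs)
    nt <- round(cfg$trial_duration * cfg$et_fs)
    eeg_trials <- do.call(rbind, lapply(seq_along(labels), function(tr)
      trial_annotation((tr - 1L) * ne, tr * ne, labels[tr],
                       sprintf("P%03d", tr))))
    et_trials <- do.call(rbind, lapply(seq_along(labels), function(tr)
      trial_annotation((tr - 1L) * nt, tr * nt, labels[tr],
                       sprintf("P%03d", tr))))
    eeg <- eeg_recording(do.call(cbind, lapply(eeg_parts, function(r) r$data)),
                         fs = cfg$eeg_fs, subject_id = sid, trials = eeg_trials)
    et <- et_recording(unlist(lapply(et_parts, function(r) r$gaze_x)),
                       unlist(lapply(et_parts, function(r) r$gaze_y)),
                       unlist(lapply(et_parts, function(r) r$valid)),
                       fs = cfg$et_fs, screen_size = cfg$screen_size,
                       subject_id = sid, trials = et_trials)
    list(eeg = eeg, et = et)
  })
}

#' Write a synthetic dataset to disk in the package layout
#'
#' One directory per subject (see [read_recording()]) plus a `manifest.json`
#' recording the generator configuration, seed and per-subject label counts.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
generate_dataset <- function(cfg, out_dir) {
  if (file.exists(out_dir) && !dir.exists(out_dir))
    stop("output path exists and is not a directory: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_recordings(cfg)
  label_counts <- list()
  for (s in seq_along(recs)) {
    sid <- recs[[s]]$eeg$subject_id
    sd <- file.path(out_dir, sid)
    write_recording(recs[[s]]$eeg, sd)
    write_recording(recs[[s]]$et, sd)
    label_counts[[sid]] <- list(buy = sum(recs[[s]]$eeg$trials$label == 1L),
                                no_buy = sum(recs[[s]]$eeg$trials$label == 0L))
  }
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   subjects = names(label_counts), labels = label_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
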