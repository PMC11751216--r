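# small generator configurations shared across test files

tiny_strong_cfg <- function(seed = 1, ...) {
  synth_config_strong(seed = seed, n_subjects = 1, trials_per_subject = 6, ...)
}

tiny_null_cfg <- function(seed = 1, ...) {
  synth_config_null(seed = seed, n_subjects = 1, trials_per_subject = 6, ...)
}

# a clean sinusoidal EEG recording with one annotated trial
sine_eeg <- function(freq = 10, n = 900, fs = 300, channels = 19, amp = 1) {
  tt <- (seq_len(n) - 1) / fs
  X <- matrix(rep(amp * sin(2 * pi * freq * tt), channels), channels,
              byrow = TRUE)
  eeg_recording(X, fs = fs, trials = trial_annotation(0L, n, 1L))
}

mean_fold_accuracy <- function(cv) {
  mean(vapply(cv$fold_metrics, function(m) m$accuracy, numeric(1)))
}
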