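---
title: "Predicting consumer choice from EEG and eye tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting consumer choice from EEG and eye tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

In neuromarketing experiments a participant browses product stimuli while a
scalp EEG (here 19 channels at 300 Hz, microvolts) and a screen-based eye
tracker (gaze x/y in pixels at 120 Hz) record simultaneously, and each
product-viewing trial carries a binary outcome: the participant selected the
product (*buy*) or did not (*no-buy*). The package implements a complete
window-level classification pipeline for such data:

1. **EEG cleaning** — zero-phase Butterworth band-pass 0.5–45 Hz, Artifact
   Subspace Reconstruction (ASR) on the continuous recording, segmentation
   into 1-s windows (300 samples) with 50% overlap, and a per-window
   wavelet-threshold transient suppressor ("FORCe-style").
2. **Gaze preprocessing** — straight-line interpolation of blink gaps,
   1-s/120-sample windows with 50% overlap, rasterization of each window
   onto a 64×64 black/white gaze-plot canvas, and I-DT fixation detection.
3. **Features** — handcrafted: per-channel mean, variance, skewness and
   excess kurtosis; Welch band powers in the δ/θ/α/β/γ bands; mean and SD of
   periodized db4 DWT coefficients per level (19 values × 19 channels = 361),
   plus mean fixation duration, fixation count, mean saccade amplitude and
   saccade count (4); deep: a supervised CNN-LSTM over the 19×300 window and
   a LeNet-5 over the 64×64 gaze plot, both trained with Adam against a
   1-unit sigmoid head that is discarded for extraction.
4. **Fusion** — column-wise concatenation per aligned window pair
   (EEG-deep, ET-deep, EEG-hand, ET-hand); at the flatten layer the deep-only
   fusion is 14,016 + 2,704 = 16,720 wide.
5. **Classification** — SMOTE balancing (k = 3, random state 42) of the
   training data, then a stacking ensemble: random forest (265 trees),
   classical gradient boosting (89 stages) and XGBoost (300 rounds) feed a
   100-tree random-forest meta learner through an out-of-fold meta-feature
   matrix `Z` with one column per base learner; evaluation under stratified,
   shuffled, seeded cross-validation with accuracy, precision, recall,
   specificity, F1, the exact empirical ROC and trapezoidal AUC.

The statistical assumptions are those of any window-level decoding design:
the class signal is stationary within a trial, windows are exchangeable
*given* their trial, and the buy/no-buy label is constant over a trial.

# Deep extractor architectures

The CNN-LSTM consumes a 19×300×1 window: 3×3 valid convolution with 32
filters (320 parameters), 2×2 max pool, 3×3 convolution with 64 filters
(18,496), 2×2 max pool, flatten to 14,016, reshape to a 14,016-step sequence
of scalars, a 64-unit LSTM, dense 128 (8,320) and dense 64 (8,256) layers.
LeNet-5 consumes the 64×64×1 gaze plot: 5×5 convolution with 6 filters, 2×2
pool, 5×5 convolution with 16 filters (2,416), 2×2 pool, flatten to 2,704,
dense 120 and 84. `build_cnn_lstm()` and `build_lenet5()` assert these
shapes and expose the per-layer table.

Two published parameter counts for this architecture family are not
derivable from the declared shapes and are deliberately **not** reproduced:
a 64-unit LSTM over scalar inputs has `4·64·(1+64+1) = 16,896` parameters
(not 16,832), and a 5×5×1→6 convolution has 156 parameters (456 would imply
a 3-channel input, contradicting the single-channel canvas). The package
implements the standard formulations.

Training follows the Adam update rule (β₁ = 0.9, β₂ = 0.999, η = 1e-3,
ε = 1e-8) with mean squared error on the sigmoid output for the CNN-LSTM and
binary cross-entropy for LeNet-5 (both switchable). Feature extraction
defaults to the flatten layer because only that width composes to the
16,720-dim fusion; `last_dense` gives the compact 64/84-dim alternative.
The engine is single-precision, single-threaded and fully deterministic
given the seed (weights and epoch shuffles are drawn from R's RNG).
Flushing float denormals is enabled during compiled calls: gradients
back-propagated through 14,016 recurrent steps vanish below the normal
float range, and denormal arithmetic is pathologically slow on x86.

# The synthetic study conditions

Real neuromarketing recordings are proprietary, so the generator
(`synth_config()`, `generate_recordings()`, `generate_dataset()`) creates
paired EEG + gaze recordings with exactly the structure the pipeline
assumes:

* EEG trials are spectrally synthesized 1/√f noise restricted to 0.5–45 Hz
  at ~10 µV RMS, with the 8–13 Hz amplitude multiplied by
  `alpha_power_ratio` in buy trials. Artifacts: 50 Hz line noise (2 µV),
  blink transients (150 µV Gaussian bumps, σ = 80 ms, frontally weighted,
  ~0.5–2 Hz content) time-locked to the gaze blink gaps, and 200 ms
  wideband muscle bursts.
* Gaze trials alternate fixations (lognormal durations, mean 250 ms plus
  `fixation_duration_shift` in buy trials; 2 px jitter) with ~33 ms
  ballistic saccades whose amplitudes are gamma-distributed (mean 150 px
  plus `saccade_amplitude_shift`). Blink gaps are runs of `valid = FALSE`.
* Labels are assigned per subject by exact-count sampling
  (`round(buy_fraction · trials)`, both classes forced), so class counts
  are reproducible. The default `buy_fraction = 0.125` mirrors a typical
  supermarket-browsing selection rate (~18 of 144 products).

Two presets define the package's study conditions: `synth_config_strong()`
(balanced classes, alpha amplitude halved, fixations +200 ms, saccades
+50 px; 4 subjects × 20 3-s trials → 400 aligned windows) and
`synth_config_null()` (identical but with no class effect). The class
effects sit deliberately in the alpha band and in fixation duration — the
quantities the handcrafted features measure — so handcrafted-only ablations
are meaningful.

What the generator does **not** emulate: volume-conducted source topography
(channels are independent up to shared artifacts), non-stationarity across
a session, smooth pursuit, pupil dynamics, subject-specific spectra, or any
realistic effect size — the injected effects are strong by construction.
Passing the end-to-end tests therefore demonstrates that the pipeline
recovers a planted, detectable signal and does not hallucinate one under
the null; it says nothing about attainable accuracy on real recordings.

# Numerical and design choices

* **Band-pass realization.** The 0.5 Hz edge at fs = 300 (normalized
  3.3e-3) makes an order-8 polynomial band-pass numerically fragile; the
  filter is therefore an order-4 Butterworth high-pass cascaded with an
  order-4 low-pass, each factored analytically into second-order sections
  (bilinear transform with prewarp) and applied forward–backward. This
  keeps the filter linear to ~1e-10 relative and exactly zero-phase.
* **ASR.** Calibration selects the cleanest 25% of 0.5-s windows by robust
  RMS; the model is the PCA basis of their covariance (eigenvalue floor
  1e-12 × trace against rank deficiency) with per-component thresholds
  mean + 20 SD of calibration component RMS — the widely used conservative
  cutoff. Reconstruction zeroes offending components per 50%-overlapped
  Hann-tapered window; with nothing to remove it is the identity.
* **Wavelet cleaner.** Per channel and level, detail coefficients beyond
  `k·median(|d|)/0.6745` (k = 3) are *zeroed*, not soft-shrunk: soft
  shrinkage subtracts the threshold from every large coefficient, which
  neither removes a large transient (it survives minus a small offset) nor
  spares in-band rhythms (whose own subband sets the threshold at their
  scale). Outright rejection of robust outliers mirrors how ASR drops
  components and satisfies both goals. The blink rule zeroes only
  approximation coefficients that deviate grossly from the cross-channel
  ensemble, in channels whose approximation energy exceeds k× the median —
  zeroing a whole approximation band would delete legitimate shared slow
  activity.
* **Welch estimator.** 150-sample Hann segments with 50% overlap (three
  per 1-s window), one-sided density, 2 Hz grid; sub-2 Hz resolution is
  impossible in a 1-s window, so the δ band is represented by its single
  2 Hz bin. Bands are half-open `[low, high)` to avoid double counting.
* **DWT.** Periodized db4, 4 levels (the de-facto EEG default that fits
  300 samples); odd lengths are extended by repeating the last sample, and
  recorded lengths make the inverse exact.
* **I-DT.** Dispersion threshold 50 px and minimum duration 100 ms, the
  standard dispersion-detector defaults; blink-invalid samples break
  candidate windows.
* **Gaze plots.** `floor(x/W·64)` with clipping; binary 255 rendering by
  default (an accumulate mode exists for experimentation).
* **Stacking.** Meta features default to out-of-fold positive-class
  probabilities (`meta_input = "label"` gives the literal hard-vote
  construction). Base-learner hyperparameters beyond the tree/stage/round
  counts stay at library defaults; classical gradient boosting is realized
  as depth-3, shrinkage-0.1, unregularized boosting, distinct from the
  XGBoost base learner's defaults. Every learner is seeded and
  single-threaded, so runs are reproducible end to end.
* **SMOTE.** Applied inside each training fold by default; a `global`
  scope reproduces the leakage-prone balance-then-split variant some
  published pipelines describe. It operates on the fused feature vectors:
  interpolating raw gaze plots or multichannel EEG across modalities is
  ill-defined.
* **Cross-validation unit.** Windows from one trial overlap by 50% and
  share trial-specific realizations, so window-level folding lets the
  ensemble recognize the trial rather than the class — on null data it
  scores well above chance. The experiment profiles therefore assign folds
  by *trial* (`stratified_group_folds()`), stratified on the trial label;
  `crossvalidate()` still folds at window level when no grouping is given.
  Subject-level grouping is the natural next step when enough subjects are
  available.

# Problem sizes of the package's own experiments

`full_profile()` is the full-fidelity configuration: flatten-level 16,720-dim
fusion, stratified 10-fold CV outside and inside the stack, extractors
retrained within every training fold for 50 epochs. It is provided, and
correct, but a single strong-effect grid under it is a multi-hour
computation. The experiments the package ships and tests use
`desk_profile()`: last-dense deep features (64 + 84 dims) fused with the
365 handcrafted features, 5-fold trial-grouped outer CV, 5 internal
stacking folds (the common library default for stacking), and extractors
trained on a stratified subsample of ≤128 windows (1 CNN-LSTM epoch,
5 LeNet-5 epochs, batch 32). Each experiment grid runs on 400 windows per
dataset over three seeds.

Extractor training scope deserves care. Training a feature extractor on
windows that later sit in a test fold is leakage, and the LeNet-5
demonstrates it vividly: 64×64 binary gaze plots are near-unique
fingerprints, and even five epochs let the network associate individual
plots with their labels, lifting null-data accuracy above chance through
the ET-deep block alone. The desk profile therefore always retrains the
LeNet-5 inside each training fold (it costs about a second). The CNN-LSTM
is trained once per dataset in the desk profile — a single epoch over a
subsample leaves it measurably at chance on null data — because per-fold
retraining of the recurrent network would dominate the grid's runtime;
`full_profile()` retrains both extractors per fold, which is the fully
leakage-safe configuration. The structural contracts of the full-fidelity
path — flatten widths, fused dimensionality, layer parameter counts — are
asserted directly in the test suite, so the desk profile changes scale,
not correctness.

# Known limitations

* The CNN-LSTM's 14,016-step scalar sequence is kept as declared; gradients
  through so long a recurrence vanish, so in practice the conv stack learns
  mostly through the late timesteps. The architecture is reproduced
  faithfully rather than questioned.
* ASR here is the PCA-subspace variant with component zeroing, not the
  full covariance-interpolating reconstruction of modern toolboxes; the
  wavelet cleaner is a simplified single-stage variant of the published
  FORCe method (no ICA stage).
* The trial annotation format (half-open 0-based sample ranges in a CSV
  sidecar) is a package convention; public multimodal datasets ship in
  container formats (XDF and vendor exports) that are out of scope.
* Handcrafted ET features are computed per 1-s window, which limits
  fixation counts to small integers; per-trial feature extraction would be
  richer but breaks the window-level fusion alignment.
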