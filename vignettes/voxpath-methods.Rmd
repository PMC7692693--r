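---
title: "voxpath: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxpath: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design choices
behind `voxpath`: what the vowel simulator generates and what it leaves
out, how the acoustic features are defined and computed, the
time-frequency conventions, the classifier architectures and training
recipes, and the evaluation protocol. It states no empirical numbers
beyond what the package's tests and `scripts/acceptance.R` compute.

## The task and the recording protocol

The clinical stimulus is a sustained /a:/ phonation of at least 4 s,
recorded at 50 kHz in a quiet room at comfortable loudness. The
package's unit of analysis is a mono waveform plus its rate
(`voice_signal`), and the classification target is binary:
normal vs. pathological voice. All analyses restrict the spectral
search band to 10–8000 Hz, the range relevant for human phonation.
Absolute sound-pressure level is unrecoverable from normalized digital
samples, so loudness is not modelled anywhere.

## The vowel simulator

`generate_vowel()` implements a source-filter model:

* **Source.** One excitation per glottal cycle. Cycle periods are
  `T_i = (1/f0) * (1 + J * e_i)` and excitation amplitudes
  `A_i = 1 + S * n_i`, with `e_i`, `n_i` independent standard normal
  variates truncated at ±3σ (truncation keeps periods and amplitudes
  positive; the paper-style perturbation measures are insensitive to
  the exact tail shape). `J` and `S` are the jitter and shimmer
  fractions. Excitations are placed with band-limited (windowed-sinc)
  fractional-delay kernels, so a zero-perturbation specification is
  exactly periodic on the sample grid rather than quantized to it —
  without this, sample rounding alone injects ~0.1% of false jitter at
  typical male f0.
* **Filter.** A two-pole low-pass (corner ≈ 200 Hz) gives the pulse
  train a glottal-like spectral tilt, followed by cascaded two-pole
  resonators at the formants. Defaults are standard male /a:/ values:
  (730, 90), (1090, 110), (2440, 170) Hz (center, bandwidth). A short
  pre-roll of cycles is rendered and discarded so the filters are in
  steady state at t = 0. A full Liljencrants–Fant glottal flow model
  was considered and rejected: the perturbation-recovery contract only
  needs one well-defined excitation per cycle, and the simpler source
  keeps the ground truth exact.
* **Noise.** White Gaussian noise with power equal to
  `harmonic_power / 10^(HNR_dB/10)` is added after filtering; the
  harmonic power is measured on the noise-free intermediate signal.
  `hnr_db = Inf` is a supported sentinel meaning no noise, used for the
  exact zero-perturbation tests. The output is scaled to peak 1.
* **Ground truth.** The true `T_i`, `A_i` and onsets are attached to
  the returned signal, so detection and measurement can be validated
  against the generating process rather than against themselves.

**Cohort defaults** (`synth_param_ranges()`): normal voices draw
jitter 0.2–0.5%, shimmer 1–4%, HNR 22–32 dB, f0 100–140 Hz;
pathological voices draw jitter 2–4%, shimmer 6–12%, HNR 2–10 dB,
f0 90–150 Hz. These are typical of clinical normative data for
sustained male /a:/ (normal local jitter is well under 1%; dysphonic
voices show elevated perturbation and markedly reduced HNR) and make
the two classes separable by construction. What a passing end-to-end
test shows is therefore that the pipeline — synthesis, cycle marking,
features, folds, models, metrics — is correct, **not** that the
classifier would reach any particular accuracy on real laryngeal-cancer
voices: real pathological voices differ from this simulator in onset
dynamics, tremor, subharmonics and breath noise spectra, and real
class boundaries overlap.

## Cycle detection and the 14 acoustic features

`detect_periods()` is a two-stage detector:

1. *Frame-wise pitch track.* 40 ms frames, 10 ms hop. Each frame is
   mean-subtracted, Hann-windowed, and its autocorrelation is divided by
   the autocorrelation of the window (Boersma's normalization), so a
   perfectly periodic frame scores ≈ 1 at its period lag. Candidate
   lags are restricted to local maxima within the search band, a small
   octave cost (0.02 per octave) prefers the shortest of near-equal
   lags, and the winning lag is refined by parabolic interpolation.
   Frames whose best candidate falls below 0.3 are treated as unvoiced;
   fewer than three voiced frames is an explicit "no periodicity
   detected" error (white noise and silence take this path). Candidates
   outside 0.5×–2× the track median are discarded as octave errors.
   Because lags are capped at half the frame, a 40 ms frame resolves
   floors down to 50 Hz; if a lower floor is requested and the first
   pass finds nothing, a second pass with a longer frame covers the
   full 10 Hz bound.
2. *Cycle marking.* Starting from the strongest waveform peak (on the
   polarity with the larger excursion), successive peaks are found in
   windows of 0.7–1.3 median periods. The raw peak marks are then
   refined by matched filtering: an average-cycle template is
   cross-correlated with the signal (one FFT pass) and each mark moves
   to the interpolated correlation peak nearby. Periods are the
   refined-mark differences; the per-cycle amplitude is the
   template-projection (matched-filter) amplitude scaled to the peak
   of the template, which equals the cycle's peak |x| on a clean
   signal. Both quantities are thereby averaged over the whole cycle
   rather than read off one sample — with additive noise, single-sample
   peak positions and heights carry a noise floor that swamps
   sub-percent jitter and shimmer, while the matched-filter estimates
   suppress it by roughly the square root of the cycle length. Periods
   outside [1/8000, 1/10] s or outside 0.6×–1.6× of the track median
   are dropped.

The feature vector (`extract_features()`) has a frozen order, shared by
all feature-table models: `f0_mean_hz`, `f0_sd_hz`, `hnr_db`, five
jitter variants, six shimmer variants. F0 statistics are computed over
per-cycle instantaneous frequencies `1/T_i` (not frame-wise pitch
estimates); with cycle-accurate marks this is the more direct estimator
of cycle-to-cycle variability, which is the clinically relevant signal
here. Jitter and shimmer follow the standard definitions (window
averages of absolute deviations, normalized by the mean period or
amplitude); `ddp = 3*rap` and `dda = 3*apq3` are exact algebraic
identities and are asserted as such in the tests.

**HNR.** The degree of acoustic periodicity in the energy sense: if
`r` is the height of the normalized autocorrelation at the period lag,
`HNR = 10*log10(r/(1-r))`. For accuracy at high HNR the per-frame `r`
is re-estimated with an exactly normalized cross-correlation
coefficient (numerator and both energy terms computed on the same
overlap), which equals 1 for a strictly periodic frame regardless of
where the glottal pulses fall in the frame; window-based normalizations
compress high HNR values because pulse energy is not stationary within
a frame. `r` is averaged over frames before conversion to dB and the
result is capped at ±60 dB, preventing infinities on noiseless
synthetic input. Note that jitter and shimmer themselves reduce
measured HNR — aperiodicity is aperiodicity, whatever its source — so
HNR calibration checks use zero-perturbation signals.

## Time-frequency images

* **Normalization** (`normalize_signal()`): division by the recording's
  maximum absolute value; idempotent, sign-preserving. Downstream
  perturbation features are scale-invariant, so the order of
  normalization and resampling is immaterial for the feature path; the
  package normalizes first.
* **Downsampling** (`downsample_signal()`): polyphase anti-aliased
  resampling (`signal::resample`), output length exactly
  `round(n * target/source)`. Upsampling is refused. Rates: 16 kHz for
  the MFCC path, 4 kHz for the STFT path, 22,050 Hz for raw-audio
  1D-CNN input.
* **MFCC** (`mfcc_image()`): Hann window 2048, hop 512, centred frames
  (frame count `floor(n/hop) + 1`), 40 triangular filters on the HTK
  mel scale spanning 0 to Nyquist, log with a 1e-10 floor, orthonormal
  DCT-II keeping all 40 coefficients. The framing is chosen so a 4 s
  recording at 16 kHz (64,000 samples) gives exactly 126 frames; no
  pre-emphasis and no delta features, keeping the image a plain
  spectral-envelope map.
* **STFT** (`stft_image()`): rectangular non-overlapping 0.02 s frames,
  frame count `floor((n - frame)/hop)`; of the 41 one-sided bins of an
  80-point frame the Nyquist bin is dropped, leaving 40 rows to match
  the MFCC image height. At 4 kHz a 4 s recording gives 199 frames.
  The rectangular window makes the per-frame Parseval identity exact,
  which the tests exploit.
* **Crops** (`crop_augment()`): ten 40×40 patches per image, offsets
  uniform with replacement over the valid range, seeded per recording.
  Sampling with replacement is the simple convention consistent with
  augmentation-by-randomization; the offset list is recorded.
* **Zero padding** (`zero_pad()`): right-pad to 98,304 samples for the
  1D-CNN — the smallest multiple of the pooling product
  8·8·8·8·4 = 16,384 that holds a 4 s recording at 22,050 Hz, and the
  length that makes the flattened feature width exactly
  6 × 256 = 1536. Truncation is refused rather than silent.

## Classifier families

All six families share one `build_model()` / `train_model()` /
`predict_model()` contract (probability pair summing to 1, argmax
label), making them interchangeable in the evaluation harness.

* **SVM**: radial-basis kernel, C = 1, features standardized within the
  training fold, probability outputs via `e1071`/libsvm.
* **XGBoost**: binary logistic objective, 200 trees, depth 4, learning
  rate 0.1 (the depth-wise booster).
* **LightGBM-style booster**: the defining ingredients of LightGBM are
  histogram binning and leaf-wise (best-first) tree growth; the family
  is realized with `xgboost`'s `tree_method = "hist"`,
  `grow_policy = "lossguide"`, 16 leaves — same objective and rate.
* **ANN**: the 14 standardized features through dense 14→32→16→2 with
  ReLU; a deliberately small head since the inputs are hand-crafted.
* **1D-CNN** (raw audio): six convolution blocks — kernels of width 9,
  'same' padding, channels 16, 32, 64, 128, 256 with max pooling
  8, 8, 8, 8, 4 after the first five, and a sixth 256-channel block
  with no pool — each block conv → batch norm → ReLU; then dense
  1536 → 100 → 50 → 2. The block/pool layout preserves both the
  six-block structure and the flatten width 1536 on a 98,304-sample
  input. (Five kernel counts with a sixth pool-free block is the
  reading that makes the dense-head arithmetic come out exactly.)
* **2D-CNN** (40×40 crops): three 3×3 convolution blocks with 64, 64,
  128 channels and ReLU, a single conservative 2×2 max pool after the
  last block (the input image is already small), flatten
  20×20×128 = 51,200, dense 500 → 50 → 2 with dropout 0.3 after each
  of the first two dense layers; Glorot-uniform initialization.
  Per-recording prediction averages the recording's ten crop
  probabilities before the argmax (majority vote is available as a
  config alternative); a tie at 0.5 resolves to "normal".

**Training recipe.** Softmax cross-entropy, Adam at 1e-3
(β₁ = 0.9, β₂ = 0.999), batch size 8 (16 for crops), a fixed epoch
budget (16 for the 1D-CNN, 60 for the ANN) with the per-epoch training
loss recorded. Every source of randomness — initialization, shuffling,
dropout — flows from the model seed, so fits are bit-reproducible.
Training aborts explicitly on NaN loss and on single-class training
sets.

**Implementation note.** The network engine is the package's own: an
R-level layer graph whose 1D convolution path additionally has a
dedicated C++ (BLAS dgemm) training loop with preallocated workspaces
— raw-audio maps are ~100k positions long and per-step allocation churn
dominates otherwise. The C++ forward pass and the R engine are
cross-checked against each other bit-for-bit in the tests, and the R
engine's gradients are validated against central finite differences.

**Feature importance.** For the two boosted families,
`feature_importance()` reports normalized information gain per feature;
features never split on report 0.

## Evaluation protocol

* **Folds** (`make_folds()`): stratified by label so per-fold class
  counts differ by at most one from perfect balance; with a 50/45
  cohort and k = 5 every fold holds exactly 19 recordings.
  Stratification is adopted (rather than simple random folds) so both
  classes appear in every test fold at clinical cohort sizes.
* **Leakage rule**: for the crop path, folds are assigned at the
  recording level and all ten crops travel together; without this the
  2D path trivially leaks, since crops of one recording are nearly
  duplicates.
* **Metrics** (`eval_metrics()`): accuracy, sensitivity, specificity in
  percent, positive class = pathological (sensitivity is the cancer
  detection rate). Undefined metrics (an empty class) raise errors
  rather than returning silent zeros.
* **ROC/AUC** (`roc_auc()`): rank-based Mann–Whitney AUC with midrank
  tie handling, verified against an O(n²) pair-counting oracle and
  against pROC.
* **Confidence intervals** (`exact_binomial_ci()`): Clopper–Pearson via
  beta quantiles, percent scale, boundary conventions
  lower(0, n) = 0 and upper(n, n) = 100. At the boundary the closed
  forms `lower = (α/2)^(1/n)` (all successes) and
  `upper = 1 − (α/2)^(1/n)` (no successes) hold exactly.
* **Reports** (`evaluate_model()`): per-fold metrics with mean and
  min–max range (the across-fold dispersion), pooled test-fold
  confusion with exact CIs, pooled ROC and AUC. Metrics are computed on
  held-out folds only; each recording is tested exactly once.
* **Raters** (`rater_stats()`): the same metric row for a human
  listener's binary calls; the AUC of a binary rater reduces to
  (sensitivity + specificity)/2.

## Problem sizes and numerical conventions

The packaged tests run the full stack at deliberately small scale: a
40-recording synthetic cohort (20 per class) for the five-fold
end-to-end checks, 10 random seeds per level for jitter/shimmer
recovery, and 4 s recordings throughout — sizes chosen so the whole
suite exercises every path while remaining a desk-scale computation.
Perturbation-recovery tolerances are ±25% relative on the recovered
fraction (note that for Gaussian cycle noise the expected local jitter
is 2/√π ≈ 1.13 times the injected fraction, which the tolerance
accommodates) and ±3 dB on HNR. Numerical floors: log floor 1e-10 in
the mel spectrum, probability floor 1e-12 in the cross-entropy, batch
norm ε = 1e-5, HNR cap 60 dB. Ties: max-pool takes the first maximum;
crop sampling is with replacement; a 0.5 probability tie classifies as
normal.

## Known limitations

* The simulator's perturbation model is Gaussian and stationary;
  real dysphonia shows colored noise, tremor and nonstationarity.
* The cycle detector assumes one dominant excitation per cycle; strong
  subharmonics or diplophonia would defeat the peak-picking stage.
* PRAAT's exact cycle-marking heuristics are not reproduced; the
  features agree with the standard definitions on the detected track,
  not necessarily with PRAAT's numbers on the same file.
* The 2D-CNN trains in the R engine and is the slowest family at
  realistic crop counts; it is exercised at reduced scale in the tests.
* Female voices are out of scope throughout (the clinical cohorts the
  protocol derives from are male), as is any claim of clinical-grade
  accuracy.
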