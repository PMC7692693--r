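test_that("period detection is cycle-accurate on a periodic vowel", {
  v <- vowel_120()
  tr <- detect_periods(v)
  # every period within 0.1% of 1/120 s
  expect_true(all(abs(tr$periods_s * 120 - 1) < 0.001))
  expect_equal(length(tr$periods_s), length(tr$peak_amps))
  expect_true(all(diff(tr$onsets_s) > 0))
})

test_that("detected periods match the generator ground truth cycle-for-cycle", {
  v <- perturbed_vowel()
  tr <- detect_periods(v)
  gt <- attr(v, "ground_truth")$periods_s
  # align by nearest onset: both sequences cover the same cycles up to
  # boundary trimming
  n <- min(length(tr$periods_s), length(gt))
  off_det <- tr$onsets_s[1L]
  gt_on <- attr(v, "ground_truth")$onsets_s
  k0 <- which.min(abs(gt_on - off_det))
  m <- min(length(gt) - k0 + 1L, length(tr$periods_s))
  rmse <- sqrt(mean((tr$periods_s[1:m] - gt[k0:(k0 + m - 1L)])^2))
  expect_lt(rmse / mean(gt), 0.05)
})

test_that("white noise and silence are rejected as unvoiced", {
  set.seed(1)
  expect_error(detect_periods(voice_signal(rnorm(25000), 50000)),
               "no periodicity")
  expect_error(detect_periods(voice_signal(numeric(30000), 50000)), "silent")
  expect_error(detect_periods(voice_signal(rnorm(1000), 50000)), "0.5 s")
})

test_that("jitter measures match hand-evaluated definitions", {
  # constant periods: all zero
  expect_equal(unname(jitter_measures(track(rep(10, 6)))), rep(0, 5))
  # alternating 10 / 10.5 ms
  j <- jitter_measures(track(c(10, 10.5, 10, 10.5, 10, 10.5)))
  expect_equal(j[["local"]], 0.5 / 10.25, tolerance = 1e-12)
  expect_equal(j[["local_absolute_s"]], 5e-4, tolerance = 1e-12)
  # rap: every inner period deviates by |10.5 - 61/6| = 1/3 ms from its
  # 3-point window mean
  expect_equal(j[["rap"]], (1 / 3) / 10.25, tolerance = 1e-12)
  # ppq5: both centre cycles deviate by 0.2 ms from their 5-point window
  # means (10.2 and 10.3)
  expect_equal(j[["ppq5"]], 0.2 / 10.25, tolerance = 1e-12)
  expect_equal(j[["ddp"]], 3 * j[["rap"]], tolerance = 1e-14)
})

test_that("shimmer measures match hand-evaluated definitions", {
  amps <- rep(c(1.0, 1.1), 6)
  s <- shimmer_measures(track(rep(10, 12), amps))
  expect_equal(s[["local"]], 0.1 / 1.05, tolerance = 1e-12)
  expect_equal(s[["local_db"]], 20 * log10(1.1), tolerance = 1e-12)
  expect_equal(s[["apq3"]], (0.1 / 1.5) / 1.05, tolerance = 1e-12)
  expect_equal(s[["apq5"]], 0.04 / 1.05, tolerance = 1e-12)
  expect_equal(s[["apq11"]], (0.6 / 11) / 1.05, tolerance = 1e-12)
  expect_equal(s[["dda"]], 3 * s[["apq3"]], tolerance = 1e-14)
  # constant amplitudes: all zero
  expect_equal(unname(shimmer_measures(track(rep(10, 12)))), rep(0, 6))
})

test_that("ddp = 3 rap and dda = 3 apq3 hold on random tracks", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(12:60, 1L)
    tr <- period_track(runif(n, 1 / 400, 1 / 80), runif(n, 0.5, 1.5))
    j <- jitter_measures(tr)
    s <- shimmer_measures(tr)
    expect_equal(j[["ddp"]], 3 * j[["rap"]], tolerance = 1e-12)
    expect_equal(s[["dda"]], 3 * s[["apq3"]], tolerance = 1e-12)
  }
})

test_that("window preconditions give explicit insufficient-data errors", {
  expect_error(jitter_measures(track(c(10, 10.2, 10.1, 10, 10.3))),
               "at least 6")
  expect_error(shimmer_measures(track(rep(10, 11))), "at least 12")
  expect_error(shimmer_measures(track(rep(10, 12), c(rep(1, 11), 0))),
               "non-positive")
  expect_error(period_track(c(0.2, 0.01, 0.01), rep(1, 3)), "band")
})

test_that("HNR closed form and noiseless cap behave as specified", {
  # r = 0.5 (harmonic power equal to noise power) -> 0 dB
  expect_equal(voxpath:::hnr_db_from_r(0.5), 0)
  expect_equal(voxpath:::hnr_db_from_r(0.9), 10 * log10(9), tolerance = 1e-12)
  # noiseless periodic vowel sits at the 60 dB ceiling
  expect_equal(hnr(clean_vowel()), 60)
  set.seed(2)
  expect_error(hnr(voice_signal(rnorm(25000), 50000)), "no periodicity")
})

test_that("measured HNR tracks the injected noise level", {
  for (h in c(20, 30)) {
    v <- generate_vowel(vowel_spec(f0_hz = 125, hnr_db = h, seed = 3))
    expect_lt(abs(hnr(v) - h), 3)
  }
})

test_that("feature vector has the frozen 14-entry layout", {
  f <- extract_features(clean_vowel())
  expect_length(f, 14L)
  expect_identical(names(f), acoustic_feature_names())
  expect_equal(f[["f0_mean_hz"]], 125, tolerance = 1e-3)
  expect_lt(f[["f0_sd_hz"]], 0.01)
  expect_lt(f[["local_jitter"]], 1e-6)
  expect_lt(f[["local_shimmer"]], 1e-6)
  expect_equal(f[["hnr_db"]], 60)
})

test_that("features are invariant to positive rescaling of the waveform", {
  v <- perturbed_vowel()
  f1 <- extract_features(v)
  f2 <- extract_features(voice_signal(v$samples * 0.2, v$rate_hz))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("detection failures carry the file identity", {
  set.seed(3)
  expect_error(extract_features(voice_signal(rnorm(25000), 50000),
                                id = "bad.wav"),
               "bad.wav")
})

test_that("batch extraction yields one clean row per voiced recording", {
  ds <- small_cohort()
  ft <- extract_features_batch(ds)
  expect_equal(nrow(ft), nrow(ds$manifest))
  expect_true(all(is.finite(as.matrix(ft[, acoustic_feature_names()]))))
  expect_identical(ft$label, ds$manifest$label)
  # pathological recordings carry visibly higher perturbation
  jit <- ft$local_jitter
  expect_gt(min(jit[ft$label == "pathological"]),
            max(jit[ft$label == "normal"]))
})
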