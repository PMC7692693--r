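# Shared fixtures, built once per test run and memoized: vowel synthesis
# at 4 s / 50 kHz is the expensive primitive nearly every file needs.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# clean 125 Hz vowel: integer samples-per-period at 50 kHz, no
# perturbation, no noise -- the exact-zero reference
clean_vowel <- function() {
  memo("clean125", function() {
    generate_vowel(vowel_spec(f0_hz = 125, seed = 1))
  })
}

# 120 Hz vowel (non-integer period) for the printed dimension chain
vowel_120 <- function() {
  memo("clean120", function() {
    generate_vowel(vowel_spec(f0_hz = 120, seed = 1))
  })
}

# moderately perturbed, realistic test subject
perturbed_vowel <- function() {
  memo("perturbed", function() {
    generate_vowel(vowel_spec(f0_hz = 120, jitter_frac = 0.01,
                              shimmer_frac = 0.03, hnr_db = 25, seed = 7))
  })
}

# small two-class in-memory cohort (shared by classifier/evaluation tests)
small_cohort <- function() {
  memo("cohort20", function() {
    synth_dataset(10, 10, seed = 11)
  })
}

small_cohort_features <- function() {
  memo("cohort20_features", function() {
    ds <- small_cohort()
    ft <- extract_features_batch(ds)
    list(x = as.matrix(ft[, acoustic_feature_names()]), labels = ft$label,
         manifest = ds$manifest)
  })
}

# deterministic period track helper
track <- function(periods_ms, amps = NULL) {
  p <- periods_ms / 1000
  if (is.null(amps)) amps <- rep(1, length(p))
  period_track(p, amps)
}
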