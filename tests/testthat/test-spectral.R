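test_that("max-abs normalization scales, is idempotent and sign-preserving", {
  v <- voice_signal(c(0.5, -0.25, 0.1), 100)
  n1 <- normalize_signal(v)
  expect_equal(n1$samples, c(1, -0.5, 0.2))
  expect_equal(normalize_signal(n1)$samples, n1$samples)
  already <- voice_signal(c(1, -0.3), 100)
  expect_equal(normalize_signal(already)$samples, already$samples)
  expect_error(normalize_signal(voice_signal(c(0, 0), 100)), "all-zero")
})

test_that("downsampling follows the printed length arithmetic", {
  v <- vowel_120()                    # 200,000 samples at 50 kHz
  d16 <- downsample_signal(v, 16000)
  expect_length(d16$samples, 64000L)
  expect_equal(d16$rate_hz, 16000)
  d22 <- downsample_signal(v, 22050)
  expect_length(d22$samples, 88200L)
  expect_error(downsample_signal(d16, 50000), "upsampling")
})

test_that("an in-band tone keeps its spectral peak after resampling", {
  tone <- voice_signal(sin(2 * pi * 100 * (0:199999) / 50000), 50000)
  d <- downsample_signal(tone, 16000)
  spec <- Mod(stats::fft(d$samples))[1:32000]
  peak_hz <- (which.max(spec) - 1) * 16000 / length(d$samples)
  expect_equal(peak_hz, 100, tolerance = 1e-6)
})

test_that("MFCC image of the downsampled vowel is 40 x 126", {
  m <- mfcc_image(downsample_signal(vowel_120(), 16000))
  expect_s3_class(m, "spectral_image")
  expect_equal(dim(m$values), c(40L, 126L))
  expect_true(all(is.finite(m$values)))
  expect_error(mfcc_image(voice_signal(rnorm(1000), 16000)), "window")
})

test_that("MFCC frame count equals the brute-force frame enumerator", {
  # enumerate centred frames directly: a frame exists for every window
  # centre 0, hop, 2*hop, ... that lies inside the signal
  brute_frames <- function(n, hop = 512L) {
    length(seq(0L, n, by = hop))
  }
  set.seed(5)
  for (n in sample(2048:70000, 8L)) {
    m <- mfcc_image(voice_signal(rnorm(n), 16000))
    expect_equal(ncol(m$values), n %/% 512L + 1L)
    expect_equal(ncol(m$values), brute_frames(n))
  }
})

test_that("constant signal gives identical MFCC frames", {
  m <- mfcc_image(voice_signal(numeric(16000) + 0, 16000))
  expect_true(all(abs(m$values - m$values[, 1L]) < 1e-9))
})

test_that("STFT image of a 4 s signal at 4 kHz is 40 x 199", {
  s <- stft_image(downsample_signal(vowel_120(), 4000))
  expect_equal(dim(s$values), c(40L, 199L))
  expect_equal(s$frame_len, 80L)
  expect_equal(s$hop, 80L)
})

test_that("a bin-centred tone concentrates in a single STFT row", {
  # 500 Hz = bin 10 of an 80-point frame at 4 kHz
  tone <- voice_signal(sin(2 * pi * 500 * (0:15999) / 4000), 4000)
  s <- stft_image(tone)
  row_power <- rowSums(s$values^2)
  expect_equal(which.max(row_power), 11L)  # row 11 = bin 10 (0-based)
  expect_gt(row_power[11L] / sum(row_power), 0.99)
})

test_that("STFT frame magnitudes satisfy Parseval's identity", {
  v <- downsample_signal(perturbed_vowel(), 4000)
  fr <- v$samples[161:240]             # one interior frame
  full <- Mod(stats::fft(fr))^2
  expect_equal(sum(full) / 80, sum(fr^2), tolerance = 1e-10)
  # the 40 retained rows are the first 40 one-sided bins
  s <- stft_image(v)
  expect_equal(s$values[, 3L], Mod(stats::fft(fr))[1:40], tolerance = 1e-10)
})

test_that("crop augmentation yields ten 40x40 seed-reproducible patches", {
  img <- mfcc_image(downsample_signal(vowel_120(), 16000))
  cs <- crop_augment(img, seed = 5)
  expect_length(cs$patches, 10L)
  expect_true(all(vapply(cs$patches, function(p) all(dim(p) == c(40L, 40L)),
                         logical(1L))))
  expect_true(all(cs$offsets >= 0 & cs$offsets <= ncol(img$values) - 40L))
  cs2 <- crop_augment(img, seed = 5)
  expect_identical(cs$offsets, cs2$offsets)
  expect_false(identical(cs$offsets, crop_augment(img, seed = 6)$offsets))
  # patches really are windows of the image
  o <- cs$offsets[1L]
  expect_identical(cs$patches[[1L]], img$values[, (o + 1L):(o + 40L)])
})

test_that("a 40-frame image can only be cropped to itself", {
  img <- spectral_image(matrix(rnorm(1600), 40, 40), "mfcc", 16000, 2048L, 512L)
  cs <- crop_augment(img, seed = 1)
  expect_true(all(cs$offsets == 0L))
  expect_identical(cs$patches[[3L]], img$values)
  narrow <- spectral_image(matrix(rnorm(40 * 39), 40, 39), "mfcc", 16000,
                           2048L, 512L)
  expect_error(crop_augment(narrow), "fewer than 40")
})

test_that("zero padding reaches the 1D-CNN input length exactly", {
  v <- downsample_signal(vowel_120(), 22050)   # 88,200 samples
  zp <- zero_pad(v)
  expect_length(zp$samples, 98304L)
  expect_equal(sum(abs(zp$samples[88201:98304])), 0)
  expect_identical(zp$samples[1:88200], v$samples)
  # identity when already at target
  expect_identical(zero_pad(zp)$samples, zp$samples)
  expect_error(zero_pad(zp, 90000L), "truncation")
  # 98,304 = 6 x 16,384: the pooling chain leaves 6 positions x 256
  # channels = the printed flatten width 1536
  expect_equal(98304L / (8L * 8L * 8L * 8L * 4L) * 256L, 1536L)
})
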