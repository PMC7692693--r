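#' Max-abs normalization
#'
#' Divides the waveform by its maximum absolute value so recordings made
#' at different mouth-to-microphone distances share a common amplitude
#' scale. Idempotent and sign-preserving.
#'
#' @param signal A [voice_signal()] with at least one non-zero sample.
#' @return A [voice_signal()] with `max(abs(samples)) == 1`.
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "voice_signal"))
  m <- max(abs(signal$samples))
  if (m == 0) stop("normalize_signal: all-zero signal")
  voice_signal(signal$samples / m, signal$rate_hz)
}

#' Anti-aliased downsampling
#'
#' Resamples to a lower rate through a polyphase anti-aliasing filter
#' (`signal::resample`). Output length is exactly
#' `round(n * target_hz / rate_hz)`.
#'
#' @param signal A [voice_signal()].
#' @param target_hz Target rate, strictly below the current rate.
#' @return A [voice_signal()] at `target_hz`.
#' @export
downsample_signal <- function(signal, target_hz) {
  stopifnot(inherits(signal, "voice_signal"))
  if (target_hz >= signal$rate_hz) {
    stop("downsample_signal: target rate must be below the signal rate (upsampling unsupported)")
  }
  target_hz <- as.numeric(target_hz)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  g <- gcd2(round(target_hz), round(signal$rate_hz))
  y <- signal::resample(signal$samples, round(target_hz) / g,
                        round(signal$rate_hz) / g)
  n_out <- round(as.numeric(length(signal$samples)) * target_hz /
                   signal$rate_hz)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  voice_signal(y, target_hz)
}

#' Construct a spectral image
#'
#' A coefficients-by-frames matrix (MFCC or STFT magnitude) plus its
#' framing metadata; the substrate for the 2D-CNN path.
#'
#' @param values Numeric matrix, 40 rows.
#' @param kind `"mfcc"` or `"stft"`.
#' @param source_rate_hz Rate of the transformed signal in Hz.
#' @param frame_len,hop Framing, in samples.
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(values, kind, source_rate_hz, frame_len, hop) {
  kind <- match.arg(kind, c("mfcc", "stft"))
  if (!is.matrix(values) || nrow(values) != 40L) {
    stop("spectral_image: values must be a matrix with 40 coefficient rows")
  }
  if (!all(is.finite(values))) stop("spectral_image: non-finite values")
  structure(list(values = values, kind = kind,
                 source_rate_hz = source_rate_hz,
                 frame_len = frame_len, hop = hop),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("<spectral_image:%s> %d x %d (rate %g Hz, frame %d, hop %d)\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$source_rate_hz, x$frame_len, x$hop))
  invisible(x)
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# 40 triangular filters on the mel scale over [0, rate/2], applied to a
# one-sided power spectrum of n_fft bins
mel_filterbank <- function(n_mel, n_fft, rate) {
  n_bins <- n_fft %/% 2L + 1L
  f_bins <- (0:(n_bins - 1L)) * rate / n_fft
  m_pts <- seq(hz_to_mel(0), hz_to_mel(rate / 2), length.out = n_mel + 2L)
  f_pts <- mel_to_hz(m_pts)
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- f_pts[m]; ce <- f_pts[m + 1L]; hi <- f_pts[m + 2L]
    up <- (f_bins - lo) / (ce - lo)
    dn <- (hi - f_bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II matrix (n_out x n_in)
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  j <- 0:(n_in - 1L)
  m <- sqrt(2 / n_in) * cos(outer(k, (j + 0.5) * pi / n_in))
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

#' MFCC time-spectral image
#'
#' Mel-frequency cepstral coefficients per frame: Hann-windowed power
#' spectrum, 40 triangular mel filters spanning 0 to Nyquist, log with a
#' 1e-10 floor, then an orthonormal DCT-II keeping all 40 coefficients.
#' Framing is centred (the signal is zero-padded by half a window on
#' each side), so the frame count is `floor(n / hop) + 1`; a
#' 64,000-sample signal at 16 kHz with the default window 2048 and hop
#' 512 yields a 40 x 126 image.
#'
#' @param signal A [voice_signal()], nominally at 16 kHz.
#' @param n_mel Number of mel filters (rows), default 40.
#' @param frame_len Window length in samples (default 2048).
#' @param hop Hop in samples (default 512).
#' @return A [spectral_image()] of kind `"mfcc"`.
#' @export
mfcc_image <- function(signal, n_mel = 40L, frame_len = 2048L, hop = 512L) {
  stopifnot(inherits(signal, "voice_signal"))
  x <- signal$samples
  n <- length(x)
  if (n < frame_len) stop("mfcc_image: signal shorter than one analysis window")
  n_frames <- n %/% hop + 1L
  half <- frame_len %/% 2L
  xp <- c(numeric(half), x, numeric(frame_len))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame_len - 1L)) / frame_len)
  fb <- mel_filterbank(n_mel, frame_len, signal$rate_hz)
  dct <- dct_matrix(n_mel, n_mel)
  n_bins <- frame_len %/% 2L + 1L
  pw <- vapply(seq_len(n_frames), function(i) {
    fr <- xp[((i - 1L) * hop + 1L):((i - 1L) * hop + frame_len)] * win
    Mod(stats::fft(fr))[1:n_bins]^2
  }, numeric(n_bins))
  vals <- dct %*% log(pmax(fb %*% pw, 1e-10))
  spectral_image(vals, "mfcc", signal$rate_hz, frame_len, as.integer(hop))
}

#' STFT magnitude image
#'
#' Short-time Fourier magnitude with non-overlapping rectangular frames
#' of 0.02 s. The frame count convention is
#' `floor((n - frame_len) / hop)`; at 4 kHz (frame = hop = 80 samples) a
#' 4 s signal gives 199 frames. The 41 one-sided bins of an 80-point
#' frame are truncated to 40 rows by dropping the Nyquist bin, matching
#' the MFCC image height.
#'
#' @param signal A [voice_signal()], nominally at 4 kHz.
#' @param frame_s Frame length in seconds (default 0.02, no overlap).
#' @return A [spectral_image()] of kind `"stft"`.
#' @export
stft_image <- function(signal, frame_s = 0.02) {
  stopifnot(inherits(signal, "voice_signal"))
  x <- signal$samples
  frame_len <- round(frame_s * signal$rate_hz)
  hop <- frame_len
  n_frames <- (length(x) - frame_len) %/% hop
  if (n_frames < 1L) stop("stft_image: signal shorter than one analysis frame")
  n_keep <- 40L
  mags <- vapply(seq_len(n_frames), function(i) {
    fr <- x[((i - 1L) * hop + 1L):((i - 1L) * hop + frame_len)]
    Mod(stats::fft(fr))[1:n_keep]
  }, numeric(n_keep))
  spectral_image(mags, "stft", signal$rate_hz, as.integer(frame_len),
                 as.integer(hop))
}

#' Random 40x40 crops of a spectral image
#'
#' Draws `n` contiguous-frame patches of the full 40 coefficient rows by
#' 40 frames, with frame offsets uniform (with replacement) over the
#' valid range. Ten crops per image is the augmentation factor used for
#' the 2D-CNN path.
#'
#' @param image A [spectral_image()] with at least 40 frames.
#' @param n Number of crops (default 10).
#' @param seed Integer seed; the offset list is reproducible.
#' @param source_id Optional recording identity carried with the crops.
#' @return An object of class `crop_set`: `patches` (list of 40x40
#'   matrices), `offsets` (0-based frame offsets), `source_id`.
#' @export
crop_augment <- function(image, n = 10L, seed = 1L, source_id = NA_character_) {
  stopifnot(inherits(image, "spectral_image"))
  n_frames <- ncol(image$values)
  if (n_frames < 40L) stop("crop_augment: image has fewer than 40 frames")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  offsets <- sample.int(n_frames - 40L + 1L, n, replace = TRUE) - 1L
  patches <- lapply(offsets, function(o) image$values[, (o + 1L):(o + 40L)])
  structure(list(patches = patches, offsets = offsets, source_id = source_id),
            class = "crop_set")
}

#' Right zero padding
#'
#' Pads a signal with trailing zeros to exactly `target_len` samples.
#' The default target, 98,304 samples, is the smallest multiple of the
#' 1D-CNN pooling product (8*8*8*8*4 = 16,384) that holds a 4 s
#' recording downsampled to 22,050 Hz (88,200 samples), and maps to a
#' flattened feature width of 6 x 256 = 1536. Truncation is refused.
#'
#' @param signal A [voice_signal()].
#' @param target_len Target length in samples.
#' @return A [voice_signal()] of exactly `target_len` samples.
#' @export
zero_pad <- function(signal, target_len = 98304L) {
  stopifnot(inherits(signal, "voice_signal"))
  n <- length(signal$samples)
  if (n > target_len) {
    stop("zero_pad: signal longer than target (truncation refused; crop first)")
  }
  voice_signal(c(signal$samples, numeric(target_len - n)), signal$rate_hz)
}
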