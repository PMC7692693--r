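#' Construct a voice signal
#'
#' The common currency between all modules: a finite mono waveform plus its
#' sampling rate. Samples are dimensionless amplitudes, nominally in
#' \[-1, 1\] after [normalize_signal()].
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @return An object of class `voice_signal` with elements `samples` and
#'   `rate_hz`.
#' @export
voice_signal <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("voice_signal: 'samples' must be non-empty")
  }
  if (!all(is.finite(samples))) {
    stop("voice_signal: all samples must be finite")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("voice_signal: 'rate_hz' must be a single positive number")
  }
  structure(list(samples = samples, rate_hz = as.numeric(rate_hz)),
            class = "voice_signal")
}

#' @export
print.voice_signal <- function(x, ...) {
  cat(sprintf("<voice_signal> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, max(abs(x$samples))))
  invisible(x)
}

#' @export
length.voice_signal <- function(x) length(x$samples)

#' Duration of a voice signal in seconds
#' @param signal A `voice_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "voice_signal"))
  length(signal$samples) / signal$rate_hz
}
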