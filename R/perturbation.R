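#' Construct a period track
#'
#' The substrate for all perturbation measures: ordered glottal cycle
#' durations with the per-cycle peak amplitude and cycle onset times.
#'
#' @param periods_s Cycle durations in seconds; each must lie in the
#'   \[1/8000, 1/10\] s band implied by the 10--8000 Hz analysis range.
#' @param peak_amps Per-cycle peak absolute amplitudes (dimensionless).
#' @param onsets_s Cycle start times in seconds, strictly increasing.
#'   Defaults to the cumulated periods.
#' @return An object of class `period_track`.
#' @export
period_track <- function(periods_s, peak_amps,
                         onsets_s = cumsum(c(0, periods_s[-length(periods_s)]))) {
  periods_s <- as.numeric(periods_s)
  peak_amps <- as.numeric(peak_amps)
  onsets_s <- as.numeric(onsets_s)
  if (length(periods_s) < 3L) {
    stop("period_track: need at least 3 cycles for any perturbation measure")
  }
  if (length(peak_amps) != length(periods_s) ||
      length(onsets_s) != length(periods_s)) {
    stop("period_track: periods_s, peak_amps and onsets_s must have equal length")
  }
  if (!all(is.finite(periods_s)) || !all(is.finite(peak_amps))) {
    stop("period_track: non-finite entries")
  }
  if (any(periods_s < 1 / 8000 - 1e-12) || any(periods_s > 1 / 10 + 1e-12)) {
    stop("period_track: periods outside the [1/8000, 1/10] s band")
  }
  if (any(diff(onsets_s) <= 0)) {
    stop("period_track: onsets must be strictly increasing")
  }
  structure(list(periods_s = periods_s, peak_amps = peak_amps,
                 onsets_s = onsets_s),
            class = "period_track")
}

#' @export
print.period_track <- function(x, ...) {
  cat(sprintf("<period_track> %d cycles, mean period %.4f ms (f0 ~ %.1f Hz)\n",
              length(x$periods_s), 1000 * mean(x$periods_s),
              1 / mean(x$periods_s)))
  invisible(x)
}

# frame-wise normalized autocorrelation pitch candidates (Boersma-style):
# each frame is mean-subtracted, Hann-windowed, and its autocorrelation is
# divided by the autocorrelation of the window itself so that a perfectly
# periodic frame scores ~1 at its period lag. Candidate lags are local
# maxima only (the near-zero-lag smoothness plateau is never a candidate)
# and a small octave cost prefers the shortest of near-equal lags, since
# period multiples score the same for a periodic signal. Lags are capped
# at half the frame, so the frame length bounds the searchable pitch
# floor; `pitch_frames` below retries with a longer frame when a low
# floor is requested.
# Returns data.frame(time, period_s, strength) for frames whose best
# candidate exceeds `voicing_min`.
autocorr_pitch_frames <- function(x, rate, f0_min, f0_max,
                                  frame_s = 0.04, hop_s = 0.01,
                                  voicing_min = 0.3, octave_cost = 0.02) {
  nfr <- round(frame_s * rate)
  hop <- round(hop_s * rate)
  n <- length(x)
  if (n < nfr) return(data.frame(time = numeric(0), period_s = numeric(0),
                                 strength = numeric(0)))
  starts <- seq(1L, n - nfr + 1L, by = hop)
  lag_min <- max(2L, floor(rate / f0_max))
  lag_max <- min(floor(nfr / 2), ceiling(rate / f0_min))
  if (lag_max <= lag_min + 1L) {
    return(data.frame(time = numeric(0), period_s = numeric(0),
                      strength = numeric(0)))
  }
  nfft <- 2L^ceiling(log2(2L * nfr))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfr - 1L)) / (nfr - 1L))
  spw <- stats::fft(c(win, numeric(nfft - nfr)))
  acw <- Re(stats::fft(spw * Conj(spw), inverse = TRUE))[1:(lag_max + 2L)]
  rw <- acw / acw[1L]
  out <- lapply(starts, function(s) {
    w <- x[s:(s + nfr - 1L)]
    w <- (w - mean(w)) * win
    if (sum(w^2) <= 0) return(NULL)
    sp <- stats::fft(c(w, numeric(nfft - nfr)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:(lag_max + 2L)]
    rl <- (ac / ac[1L] / rw)[-1L]      # rl[l] = normalized r at lag l
    loc <- which(diff(sign(diff(rl))) == -2L) + 1L
    loc <- loc[loc >= lag_min & loc <= lag_max]
    if (length(loc) == 0L) return(NULL)
    score <- pmin(1, rl[loc]) - octave_cost * log2(loc / lag_min)
    lag <- loc[which.max(score)]
    y1 <- rl[lag - 1L]; y2 <- rl[lag]; y3 <- rl[lag + 1L]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    d <- max(-0.5, min(0.5, d))
    c(time = (s - 1L + nfr / 2) / rate, period_s = (lag + d) / rate,
      strength = min(1, y2 - 0.25 * (y1 - y3) * d))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(time = numeric(0), period_s = numeric(0),
                                      strength = numeric(0)))
  out <- as.data.frame(out)
  out[out$strength >= voicing_min, , drop = FALSE]
}

# two-pass wrapper: a 40 ms frame resolves floors down to 50 Hz; if that
# yields too few voiced frames and the requested floor is lower, retry
# with a frame long enough to hold two periods at the floor.
pitch_frames <- function(x, rate, f0_min, f0_max, voicing_min = 0.3) {
  eff_min <- max(f0_min, 50)
  cand <- autocorr_pitch_frames(x, rate, eff_min, f0_max,
                                voicing_min = voicing_min)
  if (nrow(cand) < 3L && f0_min < 50) {
    cand <- autocorr_pitch_frames(x, rate, f0_min, f0_max,
                                  frame_s = 2.2 / f0_min,
                                  voicing_min = voicing_min)
  }
  cand
}

# parabolic refinement of a sample-domain peak position
refine_peak <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(as.numeric(i))
  y1 <- x[i - 1L]; y2 <- x[i]; y3 <- x[i + 1L]
  den <- y1 - 2 * y2 + y3
  d <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
  i + max(-0.5, min(0.5, d))
}

# matched-filter refinement of cycle marks: an average-cycle template is
# cross-correlated with the signal (one FFT pass) and each mark is moved
# to the interpolated correlation peak nearby. Positions and amplitudes
# are thereby averaged over the whole cycle instead of read off a single
# noisy sample, which removes most of the additive-noise floor from the
# jitter and shimmer measures. Returns refined positions (fractional
# samples), the template-projection amplitude per cycle on the
# peak-amplitude scale, or NULL when too few interior cycles exist.
refine_marks_matched <- function(x, marks, t_hat_samp) {
  n <- length(x)
  h <- max(3L, floor(0.4 * t_hat_samp))
  L <- 2L * h + 1L
  centers <- round(marks)
  ok <- centers - h >= 1L & centers + h <= n - 1L
  if (sum(ok) < 3L) return(NULL)
  tpl <- rowMeans(vapply(centers[ok], function(c0) {
    x[(c0 - h):(c0 + h)]
  }, numeric(L)))
  e2 <- sum(tpl^2)
  if (e2 <= 0) return(NULL)
  nfft <- 2L^ceiling(log2(n + L))
  # cc[t] = sum_j tpl[j] * x[t + j - 1]
  cc <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                        Conj(stats::fft(c(tpl, numeric(nfft - L)))),
                      inverse = TRUE)) / nfft
  w <- max(4L, round(0.2 * t_hat_samp))
  out <- vapply(centers, function(c0) {
    t0 <- c0 - h
    lo <- max(2L, t0 - w)
    hi <- min(n - L - 1L, t0 + w)
    if (hi <= lo + 1L) return(c(NA_real_, NA_real_))
    k <- lo - 1L + which.max(cc[lo:hi])
    y1 <- cc[k - 1L]; y2 <- cc[k]; y3 <- cc[k + 1L]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) > 1e-12) max(-0.5, min(0.5, 0.5 * (y1 - y3) / den)) else 0
    pk <- y2 - 0.25 * (y1 - y3) * d
    c(k + d + h, pk / e2)
  }, numeric(2L))
  keep <- !is.na(out[1L, ])
  if (sum(keep) < 4L) return(NULL)
  list(pos = out[1L, keep], rel_amp = out[2L, keep],
       amp_scale = max(abs(tpl)))
}

#' Detect glottal cycles
#'
#' Two-stage cycle detection: a frame-wise normalized-autocorrelation
#' pitch track (40 ms frames, 10 ms hop, parabolic interpolation of the
#' lag peak) establishes the median period, then waveform peak picking
#' anchored on that period marks the individual cycle boundaries. The
#' candidate lag search is restricted to the 10--8000 Hz band and frame
#' candidates outside 0.5x--2x the track median are discarded as octave
#' errors.
#'
#' @param signal A [voice_signal()] of at least 0.5 s.
#' @param f0_min,f0_max Pitch search band in Hz.
#' @return A [period_track()]. `peak_amps` are per-cycle maxima of the
#'   absolute sample value.
#' @export
detect_periods <- function(signal, f0_min = 10, f0_max = 8000) {
  stopifnot(inherits(signal, "voice_signal"))
  x <- signal$samples
  rate <- signal$rate_hz
  if (length(x) / rate < 0.5) {
    stop("detect_periods: signal shorter than 0.5 s")
  }
  if (max(abs(x)) == 0) {
    stop("detect_periods: silent signal")
  }
  cand <- pitch_frames(x, rate, f0_min, f0_max)
  if (nrow(cand) < 3L) {
    stop("detect_periods: no periodicity detected")
  }
  t_med <- stats::median(cand$period_s)
  ok <- cand$period_s > 0.5 * t_med & cand$period_s < 2 * t_med
  if (sum(ok) < 3L) stop("detect_periods: no periodicity detected")
  t_med <- stats::median(cand$period_s[ok])
  lag_med <- t_med * rate

  # peak picking: work on the polarity that carries the larger excursion
  s <- if (abs(max(x)) >= abs(min(x))) x else -x
  n <- length(s)
  anchor <- which.max(s[1:min(n, ceiling(2 * lag_med))])
  marks <- refine_peak(s, anchor)
  # forward pass
  repeat {
    lo <- round(marks[length(marks)] + 0.7 * lag_med)
    hi <- round(marks[length(marks)] + 1.3 * lag_med)
    if (hi > n) break
    k <- lo - 1L + which.max(s[lo:hi])
    marks <- c(marks, refine_peak(s, k))
  }
  if (length(marks) < 4L) {
    stop("detect_periods: no periodicity detected")
  }
  # matched-filter refinement of the raw peak marks (see
  # refine_marks_matched); falls back to the raw marks when the track is
  # too short to form a template
  rf <- refine_marks_matched(s, marks, lag_med)
  if (!is.null(rf)) {
    marks <- rf$pos
    amps_all <- rf$rel_amp * rf$amp_scale
  } else {
    amps_all <- vapply(seq_along(marks), function(k) {
      lo <- max(1L, round(marks[k]))
      hi <- min(n, round(marks[min(length(marks), k + 1L)]))
      max(abs(x[lo:hi]))
    }, numeric(1L))
  }
  periods <- diff(marks) / rate
  keep <- periods >= 1 / 8000 & periods <= 1 / 10 &
    periods > 0.6 * t_med & periods < 1.6 * t_med &
    amps_all[-length(amps_all)] > 0
  if (sum(keep) < 3L) stop("detect_periods: no periodicity detected")
  period_track(periods[keep], amps_all[which(keep)],
               onsets_s = (marks[which(keep)] - 1) / rate)
}

#' Jitter measures
#'
#' The five PRAAT-style frequency perturbation measures computed from a
#' cycle period sequence `T_i`:
#' * `local`: mean absolute consecutive period difference divided by the
#'   mean period;
#' * `local_absolute_s`: the same numerator, in seconds;
#' * `rap`: mean absolute deviation of each period from the 3-point
#'   moving average, divided by the mean period;
#' * `ppq5`: as `rap` with a 5-point window;
#' * `ddp`: mean absolute difference of consecutive period differences,
#'   divided by the mean period (equals `3 * rap` identically).
#'
#' @param track A [period_track()] with at least 6 periods.
#' @return Named numeric vector `(local, local_absolute_s, rap, ppq5, ddp)`.
#' @export
jitter_measures <- function(track) {
  stopifnot(inherits(track, "period_track"))
  t <- track$periods_s
  n <- length(t)
  if (n < 6L) stop("jitter_measures: need at least 6 periods (ppq5 window)")
  mt <- mean(t)
  d <- diff(t)
  local_abs <- mean(abs(d))
  rap <- mean(abs(t[2:(n - 1)] -
                    (t[1:(n - 2)] + t[2:(n - 1)] + t[3:n]) / 3)) / mt
  m5 <- (t[1:(n - 4)] + t[2:(n - 3)] + t[3:(n - 2)] + t[4:(n - 1)] + t[5:n]) / 5
  ppq5 <- mean(abs(t[3:(n - 2)] - m5)) / mt
  ddp <- mean(abs(diff(d))) / mt
  c(local = local_abs / mt, local_absolute_s = local_abs,
    rap = rap, ppq5 = ppq5, ddp = ddp)
}

#' Shimmer measures
#'
#' The six PRAAT-style amplitude perturbation measures from per-cycle
#' peak amplitudes `A_i`: `local` (mean absolute consecutive difference
#' over mean amplitude), `local_db` (mean absolute `20*log10` consecutive
#' ratio, in dB), `apq3`, `apq5`, `apq11` (mean absolute deviation from
#' the 3/5/11-point centred moving average, over the mean amplitude) and
#' `dda = 3 * apq3`.
#'
#' @param track A [period_track()] with at least 12 cycles and strictly
#'   positive amplitudes.
#' @return Named numeric vector
#'   `(local, local_db, apq3, apq5, apq11, dda)`.
#' @export
shimmer_measures <- function(track) {
  stopifnot(inherits(track, "period_track"))
  a <- track$peak_amps
  n <- length(a)
  if (any(a <= 0)) stop("shimmer_measures: non-positive peak amplitude")
  if (n < 12L) stop("shimmer_measures: need at least 12 cycles (apq11 window)")
  ma <- mean(a)
  apq <- function(w) {
    h <- (w - 1L) %/% 2L
    centers <- (h + 1L):(n - h)
    dev <- vapply(centers, function(i) {
      abs(a[i] - mean(a[(i - h):(i + h)]))
    }, numeric(1L))
    mean(dev) / ma
  }
  apq3 <- apq(3L)
  c(local = mean(abs(diff(a))) / ma,
    local_db = mean(abs(20 * log10(a[-1] / a[-n]))),
    apq3 = apq3, apq5 = apq(5L), apq11 = apq(11L), dda = 3 * apq3)
}

#' Harmonics-to-noise ratio
#'
#' Frame-wise HNR in the autocorrelation domain: within each analysis
#' frame the height `r` of the normalized autocorrelation at the
#' detected period lag estimates the periodic fraction of the frame
#' energy, so `HNR = 10*log10(r / (1 - r))`. `r` is averaged over voiced
#' frames before conversion, and the result is capped at `ceiling_db`
#' for near-perfect periodicity.
#'
#' @param signal A [voice_signal()].
#' @param f0_band `c(min_hz, max_hz)` pitch search band.
#' @param ceiling_db Cap in dB applied symmetrically (default 60).
#' @return HNR in dB.
#' @export
hnr <- function(signal, f0_band = c(10, 8000), ceiling_db = 60) {
  stopifnot(inherits(signal, "voice_signal"))
  x <- signal$samples
  rate <- signal$rate_hz
  cand <- pitch_frames(x, rate, f0_band[1L], f0_band[2L], voicing_min = 0.1)
  if (nrow(cand) < 3L) stop("hnr: no periodicity detected")
  t_med <- stats::median(cand$period_s)
  ok <- cand$period_s > 0.5 * t_med & cand$period_s < 2 * t_med
  if (sum(ok) < 3L) stop("hnr: no periodicity detected")
  lag0 <- stats::median(cand$period_s[ok]) * rate

  # refine r per frame with the exactly-normalized cross-correlation
  # coefficient: for a strictly periodic frame it equals 1 at the period
  # lag whatever the pulse placement, so high HNR is not compressed by
  # window-normalization mismatch.
  nfr <- max(round(0.04 * rate), ceiling(3 * lag0))
  hop <- round(0.02 * rate)
  n <- length(x)
  starts <- seq(1L, max(1L, n - nfr + 1L), by = hop)
  lags <- max(2L, floor(0.9 * lag0)):min(nfr - 2L, ceiling(1.1 * lag0))
  rs <- vapply(starts, function(s) {
    w <- x[s:(s + nfr - 1L)]
    w <- w - mean(w)
    r <- vapply(lags, function(l) {
      a <- w[1:(nfr - l)]
      b <- w[(1L + l):nfr]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den <= 0) 0 else sum(a * b) / den
    }, numeric(1L))
    k <- which.max(r)
    if (k > 1L && k < length(r)) {
      y1 <- r[k - 1L]; y2 <- r[k]; y3 <- r[k + 1L]
      den <- y1 - 2 * y2 + y3
      d <- if (abs(den) > 1e-12) max(-0.5, min(0.5, 0.5 * (y1 - y3) / den)) else 0
      y2 - 0.25 * (y1 - y3) * d
    } else r[k]
  }, numeric(1L))
  r <- mean(rs)
  r_cap <- 1 / (1 + 10^(-ceiling_db / 10))
  r <- max(1 - r_cap, min(r_cap, r))
  hnr_db_from_r(r)
}

# autocorrelation height at the period lag -> dB periodicity
hnr_db_from_r <- function(r) 10 * log10(r / (1 - r))

#' Names and order of the acoustic feature vector
#'
#' The frozen 14-entry order used by [extract_features()] and by every
#' feature-table classifier: F0 mean and SD, HNR, five jitter variants,
#' six shimmer variants.
#' @return Character vector of length 14.
#' @export
acoustic_feature_names <- function() {
  c("f0_mean_hz", "f0_sd_hz", "hnr_db",
    "local_jitter", "local_absolute_jitter_s", "rap_jitter",
    "ppq5_jitter", "ddp_jitter",
    "local_shimmer", "local_db_shimmer_db", "apq3_shimmer",
    "apq5_shimmer", "apq11_shimmer", "dda_shimmer")
}

#' Extract the 14 acoustic features
#'
#' Runs cycle detection and computes the full clinical perturbation
#' profile: mean and standard deviation of the per-cycle instantaneous
#' fundamental frequency (`1/T_i`), HNR, the five jitter and six shimmer
#' variants. The output order is fixed (see [acoustic_feature_names()]).
#'
#' @param signal A [voice_signal()].
#' @param id Optional identifier attached to error messages.
#' @return Named numeric vector of length 14.
#' @export
extract_features <- function(signal, id = NULL) {
  tr <- tryCatch(detect_periods(signal), error = function(e) {
    stop(sprintf("extract_features%s: %s",
                 if (is.null(id)) "" else paste0(" [", id, "]"),
                 conditionMessage(e)), call. = FALSE)
  })
  f <- 1 / tr$periods_s
  jit <- jitter_measures(tr)
  shm <- shimmer_measures(tr)
  out <- c(mean(f), stats::sd(f), hnr(signal),
           jit[["local"]], jit[["local_absolute_s"]], jit[["rap"]],
           jit[["ppq5"]], jit[["ddp"]],
           shm[["local"]], shm[["local_db"]], shm[["apq3"]],
           shm[["apq5"]], shm[["apq11"]], shm[["dda"]])
  names(out) <- acoustic_feature_names()
  out
}

#' Extract features for every recording in a dataset
#'
#' @param dataset A dataset as returned by [synth_dataset()] (in-memory
#'   signals plus manifest), or a manifest `data.frame` with a `file`
#'   column when `dir` is given.
#' @param dir Directory holding the WAV files referenced by a manifest.
#' @return `data.frame` with one row per recording: the 14 feature
#'   columns plus `file` and `label`.
#' @export
extract_features_batch <- function(dataset, dir = NULL) {
  if (is.data.frame(dataset)) {
    manifest <- dataset
    signals <- lapply(manifest$file, function(f) {
      read_wav(if (is.null(dir)) f else file.path(dir, f))
    })
  } else {
    manifest <- dataset$manifest
    signals <- dataset$signals
  }
  feats <- t(vapply(seq_along(signals), function(i) {
    extract_features(signals[[i]], id = manifest$file[i])
  }, numeric(14L)))
  out <- as.data.frame(feats)
  out$file <- manifest$file
  out$label <- manifest$label
  out
}
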