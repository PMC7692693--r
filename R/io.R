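#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the formats a clinical recording station
#' produces: mono PCM 16-bit, PCM 24-bit, or IEEE float32. Samples are
#' returned scaled to \[-1, 1\]; stereo files are refused rather than
#' silently mixed down.
#'
#' @param path Path to a WAV file.
#' @return A [voice_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) {
      stop("read_wav: no data chunk found (truncated file?): ", path)
    }
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0L) stop("read_wav: truncated chunk header: ", path)
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      if (length(raw_fmt) < 16L) stop("read_wav: truncated fmt chunk: ", path)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1L, 2L,
                           signed = FALSE, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk: ", path)
      if (fmt$channels != 1L) {
        stop("read_wav: only mono input is supported (got ", fmt$channels,
             " channels)")
      }
      raw_data <- readBin(con, "raw", sz)
      if (length(raw_data) < sz) stop("read_wav: truncated data chunk: ", path)
      samples <- decode_wav_samples(raw_data, fmt)
      return(voice_signal(samples, fmt$rate))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))  # skip, word-aligned
    }
  }
}

decode_wav_samples <- function(raw_data, fmt) {
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(raw_data, "integer", length(raw_data) %/% 2L, 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(raw_data) %/% 3L
    b <- matrix(as.integer(raw_data[seq_len(3L * n)]), 3L, n)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(raw_data, "numeric", length(raw_data) %/% 4L, 4L,
            endian = "little")
  } else {
    stop("read_wav: unsupported encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bit); expected PCM16/PCM24/float32")
  }
}

#' Write a mono WAV file
#'
#' @param signal A [voice_signal()] with samples in \[-1, 1\].
#' @param path Output path.
#' @param bits `16` (PCM) or `32` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  stopifnot(inherits(signal, "voice_signal"))
  if (!bits %in% c(16L, 32L)) stop("write_wav: bits must be 16 or 32")
  n <- length(signal$samples)
  rate <- as.integer(round(signal$rate_hz))
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")          # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(signal$samples * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(signal$samples, con, 4L, endian = "little")
  }
  invisible(path)
}

manifest_labels <- c("normal", "pathological")

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV with at least `file` and `label` columns; labels
#' come from the closed vocabulary normal/pathological, file ids must be
#' unique, and (optionally) the referenced WAV files must exist next to
#' the manifest.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that referenced files exist (default TRUE).
#' @return `data.frame` with the manifest rows.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("load_manifest: file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(m))) {
    stop("load_manifest: manifest needs 'file' and 'label' columns")
  }
  bad <- which(!m$label %in% manifest_labels)
  if (length(bad) > 0L) {
    stop("load_manifest: invalid label '", m$label[bad[1L]], "' in row ",
         bad[1L], " (allowed: ", paste(manifest_labels, collapse = ", "), ")")
  }
  if (anyDuplicated(m$file)) {
    stop("load_manifest: duplicate file ids: ",
         paste(unique(m$file[duplicated(m$file)]), collapse = ", "))
  }
  if (check_files) {
    paths <- file.path(dirname(path), m$file)
    missing <- !file.exists(paths)
    if (any(missing)) {
      stop("load_manifest: missing files: ",
           paste(m$file[missing], collapse = ", "))
    }
  }
  m
}

#' Write a dataset manifest
#'
#' @param manifest `data.frame` with `file` and `label` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (!all(c("file", "label") %in% names(manifest))) {
    stop("write_manifest: manifest needs 'file' and 'label' columns")
  }
  if (!all(manifest$label %in% manifest_labels)) {
    stop("write_manifest: invalid labels")
  }
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Default parameter ranges of the synthetic cohort
#'
#' Uniform sampling ranges for the vowel generator, per class. The
#' normal ranges reflect a healthy male sustained /a:/ (jitter well
#' under 1%, shimmer a few percent, HNR above 20 dB); the pathological
#' ranges reflect the elevated perturbation and reduced HNR of a
#' dysphonic voice. Values can be overridden via the YAML config
#' (`inst/extdata/default_config.yaml`).
#'
#' @return Nested list `normal` / `pathological`, each with `f0_hz`,
#'   `jitter_frac`, `shimmer_frac`, `hnr_db` ranges `c(lo, hi)`.
#' @export
synth_param_ranges <- function() {
  list(
    normal = list(f0_hz = c(100, 140), jitter_frac = c(0.002, 0.005),
                  shimmer_frac = c(0.01, 0.04), hnr_db = c(22, 32)),
    pathological = list(f0_hz = c(90, 150), jitter_frac = c(0.02, 0.04),
                        shimmer_frac = c(0.06, 0.12), hnr_db = c(2, 10)))
}

#' Generate a labelled synthetic vowel cohort
#'
#' Draws per-recording generator parameters uniformly from the class
#' ranges and renders each sustained vowel. With `dir = NULL` the
#' signals stay in memory; otherwise 16-bit WAV files plus a
#' `manifest.csv` (with the ground-truth parameters recorded per file)
#' are written to `dir`.
#'
#' @param n_normal,n_pathological Recordings per class.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param dir Output directory or `NULL` for in-memory.
#' @param duration_s,sample_rate_hz Recording protocol (defaults 4 s at
#'   50 kHz).
#' @param ranges Parameter ranges, defaults [synth_param_ranges()].
#' @return List with `manifest` (data.frame) and, for in-memory use,
#'   `signals` (list of [voice_signal()]).
#' @export
synth_dataset <- function(n_normal, n_pathological, seed = 1L, dir = NULL,
                          duration_s = 4, sample_rate_hz = 50000,
                          ranges = synth_param_ranges()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  labels <- c(rep("normal", n_normal), rep("pathological", n_pathological))
  n <- length(labels)
  seeds <- sample.int(2^30, n)
  runif1 <- function(r) stats::runif(1L, r[1L], r[2L])
  rows <- vector("list", n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    rg <- ranges[[labels[i]]]
    spec <- vowel_spec(f0_hz = runif1(rg$f0_hz),
                       jitter_frac = runif1(rg$jitter_frac),
                       shimmer_frac = runif1(rg$shimmer_frac),
                       hnr_db = runif1(rg$hnr_db),
                       duration_s = duration_s,
                       sample_rate_hz = sample_rate_hz,
                       seed = seeds[i])
    signals[[i]] <- generate_vowel(spec)
    rows[[i]] <- data.frame(file = sprintf("%s_%03d.wav", labels[i], i),
                            label = labels[i], f0_hz = spec$f0_hz,
                            jitter_frac = spec$jitter_frac,
                            shimmer_frac = spec$shimmer_frac,
                            hnr_db = spec$hnr_db, seed = spec$seed)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_wav(signals[[i]], file.path(dir, manifest$file[i]))
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    return(invisible(list(manifest = manifest, dir = dir)))
  }
  list(manifest = manifest, signals = signals)
}

#' Load the packaged default configuration
#'
#' YAML configuration with the synthetic-cohort parameter ranges and the
#' per-family training hyperparameters used by the command-line tools.
#'
#' @param path Optional path to a user config; defaults to the packaged
#'   file.
#' @return Nested list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "voxpath")
  }
  yaml::read_yaml(path)
}
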