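#' Construct an audio signal
#'
#' The package-wide currency for audio: a mono waveform in `[-1, 1]` with a
#' sample rate.  All processing is done in double precision; integer PCM is
#' converted only at file boundaries.
#'
#' @param samples numeric vector of finite sample values in `[-1, 1]`.
#'   Values slightly outside are clipped with a warning.
#' @param sample_rate positive integer sampling rate in Hz.
#' @return An object of class `audio_signal`: a numeric vector with a
#'   `sample_rate` attribute.
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio signal contains non-finite samples")
  sample_rate <- as.integer(sample_rate)
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate <= 0L)
    stop("sample_rate must be a single positive integer")
  if (any(abs(samples) > 1)) {
    warning("samples outside [-1, 1] clipped")
    samples <- pmin(1, pmax(-1, samples))
  }
  structure(samples, sample_rate = sample_rate, class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  sr <- sample_rate(x)
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s), peak %.3f\n",
              length(x), sr, length(x) / sr, max(abs(x))))
  invisible(x)
}

#' Sample rate of an audio signal
#' @param x an `audio_signal`.
#' @return Integer sampling rate in Hz.
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) length(x) / sample_rate(x)

# keep class/attr when subsetting
#' @export
`[.audio_signal` <- function(x, i) {
  structure(unclass(x)[i], sample_rate = attr(x, "sample_rate"),
            class = "audio_signal")
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit integer PCM (format 1) and 32-bit
#' IEEE float (format 3).  Integer samples are scaled by the type's
#' full-scale value (32768 for 16-bit), so the maximum positive code maps
#' to 32767/32768.
#'
#' @param path path to a `.wav` file.
#' @param channels how to treat multi-channel files: `"error"` (default)
#'   rejects them, `"average"` mixes down to mono.
#' @return An [audio_signal].
#' @export
read_wav <- function(path, channels = c("error", "average")) {
  channels <- match.arg(channels)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, raw(), size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), n_channels = u16(2),
                  sample_rate = u32(4), bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), size)
    } else {
      invisible(readBin(con, raw(), size + (size %% 2L)))
      next
    }
    if (size %% 2L == 1L) invisible(readBin(con, raw(), 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (!fmt$format %in% c(1, 3))
    stop("unsupported WAV encoding (format tag ", fmt$format,
         "); only PCM (1) and IEEE float (3) are supported")

  if (fmt$format == 1) {
    if (fmt$bits != 16)
      stop("only 16-bit integer PCM supported, got ", fmt$bits, "-bit")
    n <- length(data_raw) %/% 2L
    x <- readBin(data_raw, integer(), n, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else {
    if (fmt$bits != 32) stop("only 32-bit float WAV supported")
    n <- length(data_raw) %/% 4L
    x <- readBin(data_raw, numeric(), n, size = 4, endian = "little")
  }
  if (length(x) == 0L) stop("zero-length audio in ", path)

  nc <- fmt$n_channels
  if (nc > 1L) {
    if (channels == "error")
      stop("multi-channel WAV (", nc, " channels); use channels = \"average\"")
    x <- colMeans(matrix(x, nrow = nc))
  }
  audio_signal(pmin(1, pmax(-1, x)), fmt$sample_rate)
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' @param x an [audio_signal] (or numeric vector with `sample_rate`).
#' @param path output path.
#' @param sample_rate required if `x` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = NULL) {
  sr <- if (is.null(sample_rate)) attr(x, "sample_rate") else sample_rate
  if (is.null(sr)) stop("sample rate unknown; pass sample_rate")
  x <- pmin(1, pmax(-1, as.numeric(x)))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample an audio signal
#'
#' Anti-aliased polyphase resampling (via [signal::resample]) to a target
#' rate.  A no-op when the rates already match.
#'
#' @param x an [audio_signal].
#' @param target_rate desired sampling rate in Hz.
#' @return An [audio_signal] at `target_rate`.
#' @export
resample_signal <- function(x, target_rate) {
  sr <- sample_rate(x)
  target_rate <- as.integer(target_rate)
  if (sr == target_rate) return(x)
  g <- gcd_int(target_rate, sr)
  y <- signal::resample(as.numeric(x), target_rate %/% g, sr %/% g)
  audio_signal(pmin(1, pmax(-1, y)), target_rate)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `path,label,split` listing audio clips,
#' their class labels, and a split tag (`train`, `test` or `unassigned`).
#'
#' @param path CSV path.
#' @return A data.frame with columns `path`, `label`, `split`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path,label[,split]")
  if (is.null(m$split)) m$split <- "unassigned"
  bad <- setdiff(unique(m$split), c("train", "test", "unassigned"))
  if (length(bad)) stop("invalid split tag(s): ", paste(bad, collapse = ", "))
  m
}

#' Stratified train/test split of a manifest
#'
#' Per class, `ceiling(n * train_fraction)` entries are tagged `train` and
#' the remainder `test`; the assignment is deterministic for a given seed.
#' The study-design default is an 8:2 split.
#'
#' @param manifest manifest data.frame (`path`, `label`, ...).
#' @param train_fraction fraction of each class used for training, in (0, 1).
#' @param seed integer RNG seed.
#' @return The manifest with a `split` column populated.
#' @export
stratified_split <- function(manifest, train_fraction = 0.8, seed = 1L) {
  manifest <- validate_manifest(manifest)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  counts <- table(manifest$label)
  if (any(counts < 2L))
    stop("cannot stratify: class(es) with fewer than 2 entries: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  manifest$split <- "test"
  with_seed(seed, {
    for (lab in names(counts)) {
      idx <- which(manifest$label == lab)
      n_train <- ceiling(length(idx) * train_fraction)
      manifest$split[sample(idx, n_train)] <- "train"
    }
  })
  manifest
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Default run configuration
#'
#' Nested per-module settings mirroring the pipeline's training recipe:
#' pre-emphasis 0.98, 20 ms frames with 10 ms hop, 5-state left-to-right
#' HMMs with 40 EM iterations at tolerance 1e-6, context splicing of 3,
#' a 3x128 ReLU network trained with Adam at learning rate 0.003, batch
#' size 100, 10 epochs and a 0.1 validation split.
#'
#' @return A nested list of settings; see the methods vignette.
#' @export
default_config <- function() {
  list(
    audio = list(target_rate = 44100L),
    denoise = list(frame_len_s = 0.02, ar_order = 12L, noise_quantile = 0.05),
    endpoint = list(frame_len_s = 0.02, hop_s = 0.01, alpha = 5, beta = 2,
                    min_speech_s = 0.05, min_gap_s = 0.05,
                    imf_band = c(100, 14000), noise_floor_s = 0.1),
    features = list(n_filters = 26L, n_ceps = 13L, frame_len_s = 0.02,
                    hop_s = 0.01, preemphasis = 0.98, splice = 3L),
    gmm_hmm = list(n_states = 5L, n_mix = 4L, max_iter = 40L, tol = 1e-6,
                   var_floor = 1e-3),
    dnn = list(hidden = c(128L, 128L, 128L), learning_rate = 0.003,
               batch_size = 100L, epochs = 10L, max_steps_per_epoch = 200L,
               tol = 1e-6, val_fraction = 0.1, patience = 3L),
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Settings present in the file override [default_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file path.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}
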