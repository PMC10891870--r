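# ---- framing utilities shared by the front end ------------------------------

# frame a vector into full frames only (rows); no padding
frame_signal <- function(x, flen, hop) {
  n <- length(x)
  if (n < flen) return(matrix(numeric(0), 0L, flen))
  nf <- (n - flen) %/% hop + 1L
  idx <- outer(seq_len(nf) - 1L, seq_len(flen) - 1L,
               function(i, j) i * hop + j + 1L)
  matrix(x[idx], nf, flen)
}

frame_apply <- function(x, flen, hop, fun) {
  fr <- frame_signal(x, flen, hop)
  if (!nrow(fr)) return(numeric(0))
  apply(fr, 1L, fun)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

# ---- mel scale and filterbank ----------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_filters` triangular filters with centers equally spaced on the HTK
#' mel scale (`m = 2595 log10(1 + f/700)`) between `fmin` and `fmax`,
#' evaluated on the `n_fft/2 + 1` non-negative FFT bins.
#'
#' @param n_filters number of filters (default 26).
#' @param n_fft FFT length.
#' @param sample_rate sampling rate in Hz.
#' @param fmin,fmax band edges in Hz (defaults 0 and Nyquist).
#' @return An `n_filters x (floor(n_fft/2) + 1)` weight matrix.
#' @export
mel_filterbank <- function(n_filters = 26L, n_fft, sample_rate,
                           fmin = 0, fmax = sample_rate / 2) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  edges <- mel_to_hz(mels)
  n_bins <- n_fft %/% 2L + 1L
  f_bins <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  fb <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- f_bins >= lo & f_bins <= ce
    dn <- f_bins > ce & f_bins <= hi
    fb[m, up] <- (f_bins[up] - lo) / max(ce - lo, .Machine$double.eps)
    fb[m, dn] <- (hi - f_bins[dn]) / max(hi - ce, .Machine$double.eps)
  }
  fb
}

#' Center frequencies of a mel filterbank
#' @inheritParams mel_filterbank
#' @return Numeric vector of filter center frequencies in Hz.
#' @export
mel_centers <- function(n_filters = 26L, sample_rate, fmin = 0,
                        fmax = sample_rate / 2) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  mel_to_hz(mels)[2:(n_filters + 1L)]
}

#' Orthonormal DCT-II matrix
#'
#' @param n_out number of coefficients kept (rows).
#' @param n_in input length (columns).
#' @return An `n_out x n_in` matrix `D` with orthonormal rows
#'   (`D %*% t(D) = I`).
#' @export
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  j <- 0:(n_in - 1L)
  D <- sqrt(2 / n_in) * cos(pi * outer(k, j + 0.5) / n_in)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

# ---- MFCC -------------------------------------------------------------------

#' 13-dimensional MFCC features
#'
#' Standard mel-cepstral front end: pre-emphasis
#' `y[n] = x[n] - 0.98 x[n-1]`, 20 ms frames with 10 ms hop (full frames
#' only, no padding), Hamming window, FFT power spectrum, triangular mel
#' filterbank, floored log energies, orthonormal DCT-II keeping
#' coefficients 0..12 (c0 retained as the first coefficient).
#'
#' @param x an [audio_signal].
#' @param n_filters mel filters (default 26).
#' @param n_ceps cepstral coefficients kept (default 13).
#' @param frame_len_s,hop_s framing in seconds (defaults 0.02 / 0.01).
#' @param preemphasis pre-emphasis coefficient (default 0.98).
#' @param log_floor floor on filterbank energies before the log
#'   (default 1e-10).
#' @return A `T x n_ceps` matrix with attributes `sample_rate`,
#'   `frame_len_s`, `hop_s`.
#' @export
compute_mfcc <- function(x, n_filters = 26L, n_ceps = 13L,
                         frame_len_s = 0.02, hop_s = 0.01,
                         preemphasis = 0.98, log_floor = 1e-10) {
  sr <- sample_rate(x)
  flen <- as.integer(round(frame_len_s * sr))
  hop <- as.integer(round(hop_s * sr))
  xs <- as.numeric(x)
  if (length(xs) < flen)
    stop("signal too short for one frame (need >= ", flen, " samples, got ",
         length(xs), ")")
  y <- c(xs[1L], xs[-1L] - preemphasis * xs[-length(xs)])
  fr <- frame_signal(y, flen, hop)
  w <- hamming_window(flen)
  n_bins <- flen %/% 2L + 1L
  spec <- Mod(t(apply(fr, 1L, function(f) fft(f * w)[seq_len(n_bins)])))^2
  if (nrow(fr) == 1L) spec <- matrix(spec, 1L)  # apply() drops dims
  fb <- mel_filterbank(n_filters, flen, sr)
  loge <- log(pmax(spec %*% t(fb), log_floor))
  D <- dct_matrix(n_ceps, n_filters)
  out <- loge %*% t(D)
  structure(out, sample_rate = sr, frame_len_s = frame_len_s, hop_s = hop_s)
}

#' Append delta and delta-delta coefficients
#'
#' First-order dynamics use the standard regression formula with window
#' `N = 2` (denominator `2 * sum(d^2) = 10`) and edge-frame replication;
#' second-order dynamics apply the same operator to the deltas.  Columns
#' are ordered `[static | delta | delta-delta]`.
#'
#' @param static a `T x 13` static feature matrix.
#' @return A `T x 39` matrix (attributes preserved).
#' @export
add_deltas <- function(static) {
  d1 <- delta_regression(static)
  d2 <- delta_regression(d1)
  out <- cbind(static, d1, d2)
  attributes(out)[c("sample_rate", "frame_len_s", "hop_s")] <-
    attributes(static)[c("sample_rate", "frame_len_s", "hop_s")]
  out
}

delta_regression <- function(m, N = 2L) {
  m <- as.matrix(m)
  T_ <- nrow(m)
  pad <- function(t) m[pmin(pmax(t, 1L), T_), , drop = FALSE]
  num <- matrix(0, T_, ncol(m))
  for (d in seq_len(N)) {
    t <- seq_len(T_)
    num <- num + d * (pad(t + d) - pad(t - d))
  }
  num / (2 * sum(seq_len(N)^2))
}

#' Context-splice feature frames
#'
#' Row `t` of the output concatenates frames `t - context .. t + context`
#' (edge frames replicated), giving width `D * (2*context + 1)` — 273 for
#' 39-d features with the default context of 3.
#'
#' @param features a `T x D` feature matrix.
#' @param context frames of context on each side (default 3).
#' @return A `T x D*(2*context+1)` matrix.
#' @export
splice_frames <- function(features, context = 3L) {
  m <- as.matrix(features)
  T_ <- nrow(m)
  blocks <- lapply((-context):context, function(o)
    m[pmin(pmax(seq_len(T_) + o, 1L), T_), , drop = FALSE])
  do.call(cbind, blocks)
}

#' Full 39-d front end for one clip
#'
#' [compute_mfcc()] followed by [add_deltas()].
#'
#' @inheritParams compute_mfcc
#' @return A `T x 39` feature matrix.
#' @export
featurize <- function(x, n_filters = 26L, frame_len_s = 0.02, hop_s = 0.01,
                      preemphasis = 0.98) {
  add_deltas(compute_mfcc(x, n_filters = n_filters, frame_len_s = frame_len_s,
                          hop_s = hop_s, preemphasis = preemphasis))
}
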