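#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by envelope
#' sifting: at each sift the mean of the cubic-spline envelopes through the
#' local maxima and minima is subtracted until the component satisfies the
#' IMF acceptance rule (extrema and zero-crossing counts differing by at
#' most one, and a small normalized sift increment).  Decomposition stops
#' when the residual has fewer than two extrema of either kind or
#' `max_imfs` is reached.  By construction the IMFs and residual sum back
#' to the input exactly.
#'
#' @param x numeric signal (length >= 8).
#' @param max_imfs maximum number of IMFs to extract (default 10).
#' @param sift_tol normalized squared sift-increment threshold (default 0.05).
#' @param max_sifts per-IMF sift cap (default 60).
#' @return A list of class `imf_decomposition` with `imfs` (list of numeric
#'   vectors) and `residual`.
#' @export
emd <- function(x, max_imfs = 10L, sift_tol = 0.05, max_sifts = 60L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("signal too short for EMD (need >= 8 samples)")
  imfs <- list()
  resid <- x
  for (k in seq_len(max_imfs)) {
    ext <- find_extrema(resid)
    if (length(ext$max) < 2L || length(ext$min) < 2L) break
    h <- resid
    for (s in seq_len(max_sifts)) {
      ext <- find_extrema(h)
      if (length(ext$max) < 2L || length(ext$min) < 2L) break
      env_up <- spline_envelope(ext$max, h[ext$max], n)
      env_lo <- spline_envelope(ext$min, h[ext$min], n)
      m <- (env_up + env_lo) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < sift_tol && imf_criterion(h)) break
    }
    imfs[[k]] <- h
    resid <- resid - h
  }
  structure(list(imfs = imfs, residual = resid),
            class = "imf_decomposition")
}

# local extrema indices (strict sign changes of the first difference)
find_extrema <- function(x) {
  d <- diff(x)
  d <- ifelse(d == 0, .Machine$double.eps, d)  # break plateaus
  s <- sign(d)
  turn <- which(s[-1] != s[-length(s)]) + 1L
  list(max = turn[s[turn - 1L] > 0], min = turn[s[turn - 1L] < 0])
}

# cubic spline through extrema, mirrored at the boundaries to tame edge swings
spline_envelope <- function(idx, val, n) {
  if (length(idx) >= 2L) {
    li <- 2L - idx[2L]
    ri <- 2L * n - idx[length(idx) - 1L]
    idx <- c(li, idx, ri)
    val <- c(val[2L], val, val[length(val) - 1L])
  }
  spline(idx, val, xout = seq_len(n), method = "natural")$y
}

imf_criterion <- function(h) {
  ext <- find_extrema(h)
  zc <- sum(diff(sign(ifelse(h == 0, .Machine$double.eps, h))) != 0)
  abs((length(ext$max) + length(ext$min)) - zc) <= 1L
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual (n = %d)\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}

#' Plot an EMD decomposition
#' @param x an `imf_decomposition`.
#' @param ... passed to [graphics::plot].
#' @export
plot.imf_decomposition <- function(x, ...) {
  k <- length(x$imfs)
  op <- par(mfrow = c(k + 1L, 1L), mar = c(1.5, 4, 0.5, 1))
  on.exit(par(op))
  for (i in seq_len(k))
    plot(x$imfs[[i]], type = "l", ylab = paste0("IMF", i), xlab = "", ...)
  plot(x$residual, type = "l", ylab = "resid", xlab = "", ...)
  invisible(x)
}

#' Teager energy operator
#'
#' Instantaneous energy `psi[n] = x[n]^2 - x[n-1] * x[n+1]`, sensitive to
#' both amplitude and frequency; for a pure cosine `A*cos(w*n)` it is the
#' constant `A^2 * sin(w)^2`.  Endpoint samples copy the nearest interior
#' value so the output has the input's length.
#'
#' @param x numeric signal (length >= 3).
#' @return Numeric vector of per-sample Teager energy.
#' @export
teager_energy <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("Teager energy needs at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1L)] <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  psi
}

#' Short-time cepstral distance
#'
#' Per frame, the real cepstrum `c = IDFT(log|DFT(windowed frame)|)` is
#' compared with the mean cepstrum of the first `n_noise_frames` frames
#' (assumed noise-only) by Euclidean distance over quefrency bins 1..L,
#' excluding bin 0 so the measure ignores overall gain.
#'
#' @param x an [audio_signal] or numeric vector.
#' @param frame_len_s,hop_s framing in seconds (defaults 0.02 / 0.01).
#' @param sample_rate needed when `x` is a bare vector.
#' @param n_noise_frames number of leading frames forming the noise
#'   reference (default 10).
#' @param n_bins quefrency bins used in the distance (default 12).
#' @param log_floor floor inside the log (default 1e-10).
#' @return Numeric vector of per-frame distances.
#' @export
short_time_cepstral_distance <- function(x, frame_len_s = 0.02, hop_s = 0.01,
                                         sample_rate = NULL,
                                         n_noise_frames = 10L, n_bins = 12L,
                                         log_floor = 1e-10) {
  sr <- if (is.null(sample_rate)) attr(x, "sample_rate") else sample_rate
  if (is.null(sr)) stop("sample rate unknown")
  fr <- frame_signal(as.numeric(x), as.integer(round(frame_len_s * sr)),
                     as.integer(round(hop_s * sr)))
  if (nrow(fr) < 1L) stop("signal shorter than one frame")
  w <- hamming_window(ncol(fr))
  ceps <- t(apply(fr, 1L, function(f) {
    sp <- log(pmax(Mod(fft(f * w)), log_floor))
    Re(fft(sp, inverse = TRUE)) / length(sp)
  }))
  sel <- 2L:(n_bins + 1L)
  ref <- colMeans(ceps[seq_len(min(n_noise_frames, nrow(ceps))), sel,
                       drop = FALSE])
  sqrt(rowSums((ceps[, sel, drop = FALSE] -
                matrix(ref, nrow(ceps), n_bins, byrow = TRUE))^2))
}

#' Endpoint-detection configuration
#'
#' Two-level adaptive thresholds: the primary decision is a double
#' threshold on frame-level Teager energy of the selected IMF sum (high
#' threshold = noise mean + `alpha` * sd, low = mean + `beta` * sd, noise
#' statistics from the leading `noise_floor_s` of signal); the secondary
#' refinement extends candidate boundaries outward over frames whose
#' cepstral distance exceeds its own adaptive threshold.
#'
#' @param frame_len_s,hop_s framing (defaults 0.02 / 0.01 s).
#' @param alpha,beta high/low threshold multipliers (defaults 5 / 2;
#'   `beta <= alpha` required).
#' @param cd_mult cepstral-distance threshold multiplier (default 3).
#' @param min_speech_s minimum segment duration kept (default 0.05 s).
#' @param min_gap_s gaps shorter than this are merged (default 0.05 s).
#' @param noise_floor_s leading noise-statistics window (default 0.1 s).
#' @param imf_selection `"band"` keeps IMFs whose energy-weighted mean
#'   frequency lies in `imf_band`; `"top_k"` keeps the `imf_k` IMFs most
#'   correlated with the input.
#' @param imf_band Hz band for the `"band"` rule (default 100-14000).
#' @param imf_k k for the `"top_k"` rule (default 3).
#' @param teo_per_imf if `TRUE`, apply the Teager operator to each selected
#'   IMF and sum the energies instead of applying it to the IMF sum.
#' @return A list of class `endpoint_config`.
#' @export
endpoint_config <- function(frame_len_s = 0.02, hop_s = 0.01, alpha = 5,
                            beta = 2, cd_mult = 3, min_speech_s = 0.05,
                            min_gap_s = 0.05, noise_floor_s = 0.1,
                            imf_selection = c("band", "top_k"),
                            imf_band = c(100, 14000), imf_k = 3L,
                            teo_per_imf = FALSE) {
  imf_selection <- match.arg(imf_selection)
  stopifnot(beta <= alpha, frame_len_s > 0, hop_s > 0,
            min_speech_s > 0, min_gap_s > 0)
  structure(list(frame_len_s = frame_len_s, hop_s = hop_s, alpha = alpha,
                 beta = beta, cd_mult = cd_mult, min_speech_s = min_speech_s,
                 min_gap_s = min_gap_s, noise_floor_s = noise_floor_s,
                 imf_selection = imf_selection, imf_band = imf_band,
                 imf_k = imf_k, teo_per_imf = teo_per_imf),
            class = "endpoint_config")
}

# energy-weighted mean frequency of a signal, in Hz
mean_frequency <- function(x, sr) {
  sp <- Mod(fft(x))^2
  half <- seq_len(length(x) %/% 2L)
  f <- (half - 1L) * sr / length(x)
  p <- sp[half]
  if (sum(p) <= 0) return(0)
  sum(f * p) / sum(p)
}

#' Detect vocalization endpoints
#'
#' EMD-TEO/cepstral-distance voice-activity detection: the signal is
#' decomposed by [emd()], informative IMFs are selected, frame-level Teager
#' energy of their sum drives a double-threshold primary decision, and the
#' short-time cepstral distance refines the boundaries.  Segments shorter
#' than `min_speech_s` are dropped and gaps shorter than `min_gap_s`
#' merged; the result is sorted and non-overlapping.
#'
#' @param x a (denoised) [audio_signal].
#' @param config an [endpoint_config()].
#' @return A data.frame of class `segments` with columns `start`, `end`
#'   (0-based half-open sample indices), `start_s`, `end_s`.
#' @export
detect_endpoints <- function(x, config = endpoint_config()) {
  sr <- sample_rate(x)
  n <- length(x)
  flen <- as.integer(round(config$frame_len_s * sr))
  hop <- as.integer(round(config$hop_s * sr))
  empty <- segments_df(integer(0), integer(0), sr)
  if (n < flen) return(empty)

  dec <- emd(as.numeric(x))
  y <- select_imf_sum(dec, as.numeric(x), sr, config)

  if (config$teo_per_imf && length(dec$imfs)) {
    sel <- attr(y, "selected")
    teo <- Reduce(`+`, lapply(dec$imfs[sel], teager_energy))
  } else {
    teo <- teager_energy(y)
  }
  fr_e <- frame_apply(teo, flen, hop, mean)
  nf <- length(fr_e)
  if (nf < 2L) return(empty)

  n_noise <- max(2L, min(nf, as.integer(ceiling(config$noise_floor_s /
                                                config$hop_s))))
  mu <- mean(fr_e[seq_len(n_noise)])
  sdv <- sd(fr_e[seq_len(n_noise)])
  if (!is.finite(sdv) || sdv == 0) sdv <- mu * 0.1 + .Machine$double.eps
  thr_hi <- mu + config$alpha * sdv
  thr_lo <- mu + config$beta * sdv

  act <- double_threshold(fr_e, thr_hi, thr_lo)
  if (!nrow(act)) return(empty)

  # secondary refinement on cepstral distance
  cd <- short_time_cepstral_distance(as.numeric(x), config$frame_len_s,
                                     config$hop_s, sample_rate = sr,
                                     n_noise_frames = n_noise)
  cd_thr <- mean(cd[seq_len(n_noise)]) +
    config$cd_mult * max(sd(cd[seq_len(n_noise)]), .Machine$double.eps)
  for (i in seq_len(nrow(act))) {
    while (act$from[i] > 1L && cd[act$from[i] - 1L] > cd_thr)
      act$from[i] <- act$from[i] - 1L
    while (act$to[i] < nf && cd[act$to[i] + 1L] > cd_thr)
      act$to[i] <- act$to[i] + 1L
  }

  # frames -> 0-based half-open sample intervals
  start <- (act$from - 1L) * hop
  end <- pmin(n, (act$to - 1L) * hop + flen)
  seg <- merge_segments(start, end, round(config$min_gap_s * sr))
  keep <- (seg$end - seg$start) >= round(config$min_speech_s * sr)
  segments_df(seg$start[keep], seg$end[keep], sr)
}

select_imf_sum <- function(dec, x, sr, config) {
  k <- length(dec$imfs)
  if (k == 0L) {
    y <- dec$residual
    attr(y, "selected") <- integer(0)
    return(y)
  }
  sel <- if (config$imf_selection == "band") {
    mf <- vapply(dec$imfs, mean_frequency, numeric(1), sr = sr)
    which(mf >= config$imf_band[1] & mf <= min(config$imf_band[2], sr / 2))
  } else {
    co <- vapply(dec$imfs, function(im) abs(suppressWarnings(cor(im, x))),
                 numeric(1))
    co[!is.finite(co)] <- 0
    order(co, decreasing = TRUE)[seq_len(min(config$imf_k, k))]
  }
  if (!length(sel)) sel <- seq_len(k)
  y <- Reduce(`+`, dec$imfs[sel])
  attr(y, "selected") <- sel
  y
}

double_threshold <- function(e, hi, lo) {
  above_lo <- e > lo
  seeds <- which(e > hi)
  from <- integer(0); to <- integer(0)
  used <- rep(FALSE, length(e))
  for (s in seeds) {
    if (used[s]) next
    a <- s; b <- s
    while (a > 1L && above_lo[a - 1L]) a <- a - 1L
    while (b < length(e) && above_lo[b + 1L]) b <- b + 1L
    used[a:b] <- TRUE
    from <- c(from, a); to <- c(to, b)
  }
  data.frame(from = from, to = to)
}

merge_segments <- function(start, end, min_gap) {
  if (!length(start)) return(list(start = start, end = end))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  rs <- integer(0); re <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] - me <= min_gap) {
      me <- max(me, end[i])
    } else {
      rs <- c(rs, ms); re <- c(re, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(rs, ms), end = c(re, me))
}

segments_df <- function(start, end, sr) {
  structure(data.frame(start = as.integer(start), end = as.integer(end),
                       start_s = start / sr, end_s = end / sr),
            sample_rate = sr, class = c("segments", "data.frame"))
}

#' Extract a segment from a signal
#'
#' @param x an [audio_signal].
#' @param segment one row of a `segments` data.frame (0-based half-open).
#' @return The extracted [audio_signal].
#' @export
extract_segment <- function(x, segment) {
  audio_signal(as.numeric(x)[(segment$start + 1L):segment$end],
               sample_rate(x))
}

#' Plot a waveform with detected segments
#' @param x an [audio_signal].
#' @param segments a `segments` data.frame.
#' @param ... passed to [graphics::plot].
#' @export
plot_segments <- function(x, segments, ...) {
  sr <- sample_rate(x)
  t <- seq_along(x) / sr
  plot(t, as.numeric(x), type = "l", xlab = "time (s)", ylab = "amplitude",
       ...)
  if (nrow(segments)) {
    rect(segments$start_s, -1, segments$end_s, 1,
         col = adjustcolor("red", 0.15), border = NA)
    abline(v = segments$start_s, col = "red")
    abline(v = segments$end_s, col = "red", lty = 2)
  }
  invisible(x)
}
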