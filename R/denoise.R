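#' Fit an autoregressive state-space model to a frame
#'
#' Estimates AR coefficients by Yule-Walker on one analysis frame and packs
#' them into the state-space form used by the Kalman enhancer: the state
#' holds the last `order` clean samples, the transition matrix is the AR
#' companion matrix, the observation picks the newest sample, and the
#' process noise enters only the newest component with variance equal to
#' the AR residual variance.
#'
#' @param frame numeric vector (one frame of audio).
#' @param order AR model order `p` (frame must be at least `4 * order` long).
#' @return A list of class `state_space_model` with elements `ar`
#'   (coefficients), `A`, `H`, `Q`, `sigma2`, `order`, `degenerate`.
#' @export
fit_ar_state_model <- function(frame, order = 12L) {
  frame <- as.numeric(frame)
  order <- as.integer(order)
  if (length(frame) < 4L * order)
    stop("frame too short for AR order ", order,
         " (need >= ", 4L * order, " samples)")
  v <- var(frame)
  degenerate <- !is.finite(v) || v < .Machine$double.eps
  if (degenerate) {
    coefs <- numeric(order)
    sigma2 <- 0
  } else {
    fit <- tryCatch(
      ar(frame, aic = FALSE, order.max = order, method = "yule-walker",
         demean = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$ar))) {
      warning("AR fit singular; falling back to order 1")
      order <- 1L
      r1 <- sum(frame[-1] * frame[-length(frame)]) / sum(frame^2)
      coefs <- max(-0.999, min(0.999, r1))
      sigma2 <- v * (1 - coefs^2)
    } else {
      coefs <- as.numeric(fit$ar)
      sigma2 <- max(fit$var.pred, 0)
    }
  }
  A <- matrix(0, order, order)
  A[1, ] <- coefs
  if (order > 1L) A[cbind(2:order, 1:(order - 1L))] <- 1
  H <- c(1, numeric(order - 1L))
  Q <- matrix(0, order, order)
  Q[1, 1] <- sigma2
  structure(list(ar = coefs, A = A, H = H, Q = Q, sigma2 = sigma2,
                 order = order, degenerate = degenerate),
            class = "state_space_model")
}

#' Initialize a Kalman filter state
#'
#' @param model a `state_space_model`.
#' @param P0 initial covariance scale (diagonal).
#' @return A list of class `kalman_state` with `x` (state estimate), `P`
#'   (covariance) and `g` (last gain, initially zero).
#' @export
kalman_state <- function(model, P0 = 1) {
  p <- model$order
  structure(list(x = numeric(p), P = diag(P0, p), g = numeric(p)),
            class = "kalman_state")
}

#' One Kalman predict/update cycle
#'
#' Predicts the state through the AR process model, forms the gain from the
#' predicted covariance and measurement noise, and applies the additive
#' innovation update; the covariance is updated as `(I - gH)P` and
#' re-symmetrized.  Exposed mainly for testing and didactics; bulk
#' filtering uses a compiled loop.
#'
#' @param model a `state_space_model`.
#' @param state a `kalman_state`.
#' @param z observed (noisy) sample.
#' @param R measurement noise variance.
#' @return A list with `state` (updated `kalman_state`) and `filtered`
#'   (the clean-sample estimate).
#' @export
kalman_step <- function(model, state, z, R) {
  out <- kalman_filter_block(model$ar, model$sigma2, R, z, state$x, state$P)
  list(state = structure(list(x = as.numeric(out$x), P = out$P,
                              g = as.numeric(out$gain)),
                         class = "kalman_state"),
       filtered = out$filtered[1])
}

#' Kalman-filter noise reduction
#'
#' Frame-wise AR-model Kalman enhancement: the AR model is refit on each
#' 20 ms frame of the noisy signal and a sample-wise Kalman filter is run
#' through the frame, carrying state and covariance across frame
#' boundaries.  The measurement-noise variance is taken from a supplied
#' noise-only reference, a supplied value, or estimated by minimum
#' statistics as the mean power of the lowest-energy 5% of frames.
#'
#' @param x noisy [audio_signal].
#' @param frame_len_s analysis frame length in seconds (default 0.02).
#' @param ar_order AR order refit per frame (default 12).
#' @param noise_ref optional noise-only [audio_signal] used to estimate the
#'   measurement noise variance.
#' @param R optional explicit measurement noise variance (overrides
#'   estimation).
#' @param noise_quantile fraction of lowest-energy frames used by the
#'   minimum-statistics estimate (default 0.05).
#' @return Denoised [audio_signal] of the same length.
#' @export
denoise_signal <- function(x, frame_len_s = 0.02, ar_order = 12L,
                           noise_ref = NULL, R = NULL,
                           noise_quantile = 0.05) {
  sr <- sample_rate(x)
  n <- length(x)
  flen <- max(4L * ar_order, as.integer(round(frame_len_s * sr)))
  starts <- seq.int(1L, n, by = flen)

  if (is.null(R)) {
    R <- if (!is.null(noise_ref)) mean(as.numeric(noise_ref)^2)
         else estimate_noise_power(as.numeric(x), flen, noise_quantile)
  }
  R <- max(R, 1e-12)

  xs <- as.numeric(x)
  out <- numeric(n)
  model <- NULL
  st <- NULL
  for (s in starts) {
    e <- min(s + flen - 1L, n)
    frame <- xs[s:e]
    if (length(frame) >= 4L * ar_order) {
      model <- fit_ar_state_model(frame, ar_order)
      if (model$degenerate) model$sigma2 <- 0
    } else if (is.null(model)) {
      model <- fit_ar_state_model(rep(frame, length.out = 4L * ar_order),
                                  ar_order)
    }
    if (is.null(st)) st <- kalman_state(model, P0 = R)
    res <- kalman_filter_block(model$ar, model$sigma2, R, frame, st$x, st$P)
    out[s:e] <- res$filtered
    st$x <- as.numeric(res$x)
    st$P <- res$P
  }
  out[!is.finite(out)] <- 0
  audio_signal(pmin(1, pmax(-1, out)), sr)
}

# mean power of the lowest-energy fraction of frames (minimum statistics)
estimate_noise_power <- function(x, flen, q = 0.05) {
  n <- length(x)
  nf <- max(1L, n %/% flen)
  pw <- vapply(seq_len(nf), function(i) {
    seg <- x[((i - 1L) * flen + 1L):min(i * flen, n)]
    mean(seg^2)
  }, numeric(1))
  k <- max(1L, ceiling(q * nf))
  mean(sort(pw)[seq_len(k)])
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(sum(clean^2) / sum((test - clean)^2))`.  A zero residual
#' (identical signals) is reported as `cap` dB.
#'
#' @param clean reference signal.
#' @param test signal under test (same length).
#' @param cap ceiling in dB for a zero residual (default 120).
#' @return SNR in dB.
#' @export
snr_db <- function(clean, test, cap = 120) {
  clean <- as.numeric(clean); test <- as.numeric(test)
  if (length(clean) != length(test)) stop("signals must have equal length")
  ps <- sum(clean^2)
  if (ps == 0) stop("all-zero clean reference")
  pn <- sum((test - clean)^2)
  if (pn == 0) return(cap)
  min(cap, 10 * log10(ps / pn))
}
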