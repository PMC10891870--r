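# shared fixtures: tiny signals, tiny HMMs, and brute-force oracles

tone <- function(freq, dur_s = 1, sr = 16000, amp = 0.5, phase = 0) {
  audio_signal(amp * sin(2 * pi * freq * seq_len(dur_s * sr) / sr + phase), sr)
}

# stable AR(2) "voice-like" signal plus white noise at a requested SNR
noisy_ar_signal <- function(n = 16000, sr = 16000, snr = 5, seed = 1) {
  set.seed(seed)
  clean <- as.numeric(stats::filter(rnorm(n), c(1.7, -0.85), "recursive"))
  clean <- 0.3 * clean / max(abs(clean))
  noise <- rnorm(n)
  noise <- noise * sqrt(sum(clean^2) / (sum(noise^2) * 10^(snr / 10)))
  list(clean = audio_signal(clean, sr),
       noisy = audio_signal(pmin(1, pmax(-1, clean + noise)), sr))
}

# K = 1 left-to-right HMM with given per-state mean rows (N x D)
ltr_hmm <- function(mean_rows, vars = 1, self = 0.6, label = "m") {
  N <- nrow(mean_rows); D <- ncol(mean_rows)
  means <- array(0, c(N, 1, D))
  means[, 1, ] <- mean_rows
  covars <- array(vars, c(N, 1, D))
  trans <- diag(self, N)
  if (N > 1) trans[cbind(seq_len(N - 1), 2:N)] <- 1 - self
  trans[N, N] <- 1
  class_hmm(means, covars, matrix(1, N, 1), trans, label)
}

# random small HMM (possibly dense transitions) for trellis fuzzing
random_hmm <- function(N = 3, D = 1, seed = 1) {
  set.seed(seed)
  means <- array(rnorm(N * D, sd = 2), c(N, 1, D))
  covars <- array(runif(N * D, 0.3, 1.5), c(N, 1, D))
  trans <- diag(runif(N, 0.3, 0.8), N)
  if (N > 1) trans[cbind(seq_len(N - 1), 2:N)] <- 1 - diag(trans)[-N]
  trans[N, N] <- 1
  class_hmm(means, covars, matrix(1, N, 1), trans, paste0("r", seed))
}

# exhaustive-path log-likelihood and best path for K = 1 models
brute_force_hmm <- function(model, obs) {
  N <- model$n_states
  T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  ll <- apply(paths, 1, function(p) {
    lp <- log(model$pi[p[1]])
    if (T_ > 1)
      for (t in 2:T_) lp <- lp + log(model$trans[p[t - 1], p[t]])
    for (t in seq_len(T_))
      lp <- lp + sum(dnorm(obs[t, ], model$means[p[t], 1, ],
                           sqrt(model$covars[p[t], 1, ]), log = TRUE))
    lp
  })
  mx <- max(ll)
  list(loglik = mx + log(sum(exp(ll - mx))),
       best_score = mx,
       best_path = as.integer(paths[which.max(ll), ]))
}

# fast sampler for K = 1 left-to-right chains: geometric state durations
simulate_ltr <- function(model, n_frames, sd_emit, seed) {
  set.seed(seed)
  a <- diag(model$trans)
  N <- model$n_states
  durs <- c(1 + rgeom(N - 1, 1 - a[-N]), n_frames)
  states <- rep(seq_len(N), durs)[seq_len(n_frames)]
  D <- model$dim
  obs <- vapply(seq_len(D), function(d)
    rnorm(n_frames, model$means[states, 1, d], sd_emit), numeric(n_frames))
  list(obs = matrix(obs, n_frames, D), states = states)
}
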