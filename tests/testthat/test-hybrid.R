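test_that("smoothed priors follow the add-one arithmetic and normalize", {
  # 10 frames all in unit 1, 25 units, delta = 1 -> p(unit 1) = 11/35
  pr <- estimate_state_priors(rep(1L, 10), 25L)
  expect_equal(pr[1], 11 / 35)
  expect_equal(sum(pr), 1)
  # equal occupancy -> uniform
  pr2 <- estimate_state_priors(rep(1:25, each = 4), 25L)
  expect_equal(pr2, rep(1 / 25, 25))
  expect_error(estimate_state_priors(integer(0), 25L), "no aligned")
})

test_that("posterior-to-likelihood conversion is a per-unit log ratio", {
  hmms <- lapply(c("a", "b"), function(l)
    ltr_hmm(matrix(rnorm(5), 5, 1), label = l))
  dnn <- dnn_init(c(7, 4, 10), seed = 1)
  hm <- hybrid_model(dnn, rep(1 / 10, 10), hmms)
  post <- matrix(1 / 10, 3, 10)
  post[1, 1] <- 0.5
  post[1, -1] <- (1 - 0.5) / 9
  sll <- scaled_log_likelihoods(hm, matrix(0, 3, 7), posteriors = post)
  expect_equal(sll[1, 1], log(0.5 / 0.25) + log(0.25 / 0.1))
  # simpler anchor: posterior 0.5 against prior 0.25
  hm2 <- hybrid_model(dnn, c(0.25, rep(0.75 / 9, 9)), hmms)
  sll2 <- scaled_log_likelihoods(hm2, matrix(0, 3, 7), posteriors = post)
  expect_equal(sll2[1, 1], log(2))
  # uniform priors preserve per-frame posterior ranking
  r1 <- t(apply(post, 1, rank))
  r2 <- t(apply(sll, 1, rank))
  expect_equal(r1, r2)
})

test_that("per-frame constants cannot change the decoding decision", {
  set.seed(20)
  hmms <- lapply(c("a", "b", "c"), function(l)
    ltr_hmm(matrix(rnorm(6), 3, 2), label = l))
  dnn <- dnn_init(c(10, 6, 9), seed = 2)
  hm <- hybrid_model(dnn, rep(1 / 9, 9), hmms)
  post <- matrix(runif(6 * 9), 6, 9)
  post <- post / rowSums(post)
  base <- decode_hybrid(hm, matrix(0, 6, 10), posteriors = post)
  # multiply each frame's posteriors by a constant (a per-frame log shift)
  shifted <- post * exp(rnorm(6))  # per-row constant factor
  out <- decode_hybrid(hm, matrix(0, 6, 10), posteriors = shifted)
  expect_equal(out$label, base$label)
  expect_equal(out$scores - base$scores,
               rep(out$scores[1] - base$scores[1], 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("tiny hybrid decoding equals brute force over admissible paths", {
  hmms <- lapply(c("a", "b"), function(l)
    ltr_hmm(matrix(c(-1, 0, 1, 2, 3, -2, 1, 0.5, 2, -1), 5, 2), label = l,
            self = 0.6))
  dnn <- dnn_init(c(5, 4, 10), seed = 3)
  priors <- rep(1 / 10, 10)
  hm <- hybrid_model(dnn, priors, hmms)
  set.seed(4)
  post <- matrix(runif(6 * 10), 6, 10)
  post <- post / rowSums(post)
  out <- decode_hybrid(hm, matrix(0, 6, 5), posteriors = post)
  sll <- scaled_log_likelihoods(hm, matrix(0, 6, 5), posteriors = post)
  for (ci in 1:2) {
    cols <- (ci - 1) * 5 + (1:5)
    paths <- as.matrix(expand.grid(rep(list(1:5), 6)))
    topo <- hmms[[ci]]
    scores <- apply(paths, 1, function(p) {
      lp <- log(topo$pi[p[1]])
      for (t in 2:6) lp <- lp + log(topo$trans[p[t - 1], p[t]])
      lp + sum(sll[cbind(1:6, cols[p])])
    })
    expect_equal(unname(out$scores[ci]), max(scores[is.finite(scores)]),
                 tolerance = 1e-10)
  }
})

test_that("a net emitting exact GMM posteriors reproduces GMM-HMM decoding", {
  # two K = 1 classes; build unit posteriors p(q|x) from the true densities
  hmms <- list(ltr_hmm(matrix(c(-2, 0, 2), 3, 1), vars = 0.6, label = "a",
                       self = 0.7),
               ltr_hmm(matrix(c(2, 0, -2), 3, 1), vars = 0.6, label = "b",
                       self = 0.7))
  obs <- simulate_hmm(hmms[[1]], 8, seed = 12)$obs
  dens <- cbind(pigvoc:::gmm_log_densities(hmms[[1]], obs)$state,
                pigvoc:::gmm_log_densities(hmms[[2]], obs)$state)
  priors <- rep(1 / 6, 6)
  post <- exp(dens) %*% diag(priors)
  post <- post / rowSums(post)
  dnn <- dnn_init(c(4, 3, 6), seed = 5)
  hm <- hybrid_model(dnn, priors, hmms)
  out <- decode_hybrid(hm, matrix(0, 8, 4), posteriors = post)
  va <- viterbi(hmms[[1]], obs)
  vb <- viterbi(hmms[[2]], obs)
  # scores differ from the GMM scores by the same path-independent constant
  expect_equal(unname(out$scores["a"] - va$log_score),
               unname(out$scores["b"] - vb$log_score), tolerance = 1e-8)
  expect_equal(out$paths[[1]], va$state_ids)
  expect_equal(out$paths[[2]], vb$state_ids)
  expect_equal(out$label,
               c("a", "b")[which.max(c(va$log_score, vb$log_score))])
})

test_that("T = 1 decoding scores reduce to the start-state entry", {
  hmms <- lapply(c("a", "b"), function(l)
    ltr_hmm(matrix(rnorm(4), 2, 2), label = l))
  dnn <- dnn_init(c(3, 2, 4), seed = 6)
  hm <- hybrid_model(dnn, c(0.4, 0.2, 0.3, 0.1), hmms)
  post <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4)
  out <- decode_hybrid(hm, matrix(0, 1, 3), posteriors = post)
  sll <- scaled_log_likelihoods(hm, matrix(0, 1, 3), posteriors = post)
  expect_equal(unname(out$scores["a"]), sll[1, 1])  # log pi(1) = 0
  expect_equal(unname(out$scores["b"]), sll[1, 3])
})
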