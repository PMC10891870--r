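test_that("initialization pools equal-duration blocks per state", {
  f <- matrix(1:10, 10, 1)  # T = 10, one feature
  m <- init_hmm(list(f), n_states = 5L, n_mix = 1L, seed = 1)
  # each state initialized from exactly 2 frames; K = 1 mean = block mean
  expect_equal(as.numeric(m$means[, 1, 1]), c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_equal(m$pi, c(1, 0, 0, 0, 0))
  expect_equal(diag(m$trans)[1:4], rep(0.5, 4))
  expect_equal(m$trans[5, 5], 1)
  # duplicating the training sequence leaves pooled statistics unchanged
  m2 <- init_hmm(list(f, f), n_states = 5L, n_mix = 1L, seed = 1)
  expect_equal(m2$means, m$means)
  expect_equal(m2$covars, m$covars)
  # sequences shorter than N are skipped, all-skipped errors
  expect_warning(init_hmm(list(f, matrix(1, 2, 1)), 5L, 1L), "skipped")
  expect_error(suppressWarnings(init_hmm(list(matrix(1, 2, 1)), 5L, 1L)),
               "at least")
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  for (s in 1:6) {
    m <- random_hmm(N = 3, D = 1, seed = s)
    set.seed(100 + s)
    obs <- matrix(rnorm(6, sd = 2), 6, 1)
    bf <- brute_force_hmm(m, obs)
    fb <- forward_backward(m, obs)
    v <- viterbi(m, obs)
    expect_equal(fb$log_likelihood, bf$loglik, tolerance = 1e-10)
    expect_equal(v$log_score, bf$best_score, tolerance = 1e-10)
    expect_equal(v$state_ids, bf$best_path)
  }
})

test_that("a single-state model reduces to the frame log-density sum", {
  m <- ltr_hmm(matrix(0.5, 1, 2), vars = 0.8)
  set.seed(4)
  obs <- matrix(rnorm(10), 5, 2)
  expected <- sum(dnorm(obs[, 1], 0.5, sqrt(0.8), log = TRUE) +
                  dnorm(obs[, 2], 0.5, sqrt(0.8), log = TRUE))
  expect_equal(forward_backward(m, obs)$log_likelihood, expected)
  v <- viterbi(m, obs)
  expect_equal(v$state_ids, rep(1L, 5))
  expect_equal(v$log_score, expected)
})

test_that("posteriors normalize and components sum to their state", {
  m <- init_hmm(list(matrix(rnorm(60), 30, 2)), 3L, 2L, seed = 2)
  obs <- matrix(rnorm(24), 12, 2)
  tr <- forward_backward(m, obs)
  expect_equal(rowSums(tr$gamma), rep(1, 12))
  expect_equal(apply(tr$gamma_mix, c(1, 2), sum), tr$gamma, tolerance = 1e-12)
  # alpha-termination equals beta-initialization
  b0 <- pigvoc:::row_logsumexp(matrix(
    log(m$pi) + pigvoc:::gmm_log_densities(m, obs)$state[1, ] +
      tr$log_beta[1, ], 1))
  expect_equal(as.numeric(b0), tr$log_likelihood, tolerance = 1e-8)
})

test_that("EM log-likelihood never decreases and preserves structure", {
  truth <- ltr_hmm(matrix(c(0, 0, 3, 3, 6, 0), 3, 2, byrow = TRUE),
                   vars = 1, self = 0.8)
  sims <- lapply(1:30, function(i) simulate_hmm(truth, 40, seed = i)$obs)
  init <- init_hmm(sims, 3L, 1L, seed = 5)
  bw <- baum_welch(init, sims, max_iter = 12L)
  expect_true(all(diff(bw$loglik) >= -1e-8))
  m <- bw$model
  expect_equal(m$pi, c(1, 0, 0))
  expect_equal(m$trans[lower.tri(m$trans)], rep(0, 3))
  expect_equal(m$trans[1, 3], 0)
  expect_equal(rowSums(m$trans), rep(1, 3))
  expect_true(all(m$covars >= 1e-3))
})

test_that("EM started at the truth barely moves on a large sample", {
  truth <- ltr_hmm(matrix(c(0, 0, 3, 3, 6, 0), 3, 2, byrow = TRUE),
                   vars = 2.5e-3, self = 0.995)
  sims <- lapply(1:60, function(i)
    simulate_ltr(truth, 800, sd_emit = 0.05, seed = 400 + i)$obs)
  bw <- baum_welch(truth, sims, max_iter = 1L, var_floor = 1e-4)
  expect_lt(max(abs(bw$model$means - truth$means)), 1e-3)
  expect_lt(max(abs(bw$model$trans - truth$trans)), 2e-3)
})

test_that("EM recovers separated parameters from simulated sequences", {
  # balanced expected durations (~T/3) so the even-division init is apt
  truth <- ltr_hmm(matrix(c(0, 0, 3, 3, 6, 0), 3, 2, byrow = TRUE),
                   vars = 1, self = 0.96)
  sims <- lapply(1:100, function(i)
    simulate_hmm(truth, 80, seed = 1000 + i)$obs)
  init <- init_hmm(sims, 3L, 1L, seed = 4)
  est <- baum_welch(init, sims, max_iter = 40L, tol = 1e-6)$model
  # states come out in temporal order under the left-to-right init
  expect_lt(max(abs(est$means[, 1, ] - truth$means[, 1, ])), 0.1)
  expect_lt(abs(est$trans[1, 2] - 0.04), 0.05)
  expect_lt(abs(est$trans[2, 3] - 0.04), 0.05)
})

test_that("Viterbi paths are non-decreasing and start in state 1", {
  truth <- ltr_hmm(matrix(c(-2, 0, 2), 3, 1), vars = 0.5, self = 0.7)
  for (s in 1:5) {
    obs <- simulate_hmm(truth, 30, seed = s)$obs
    p <- viterbi(truth, obs)$state_ids
    expect_equal(p[1], 1L)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("classification picks the generating model and breaks ties first", {
  a <- ltr_hmm(matrix(c(-3, -3, 0, 0, 3, 3), 3, 2, byrow = TRUE),
               vars = 0.5, label = "a")
  b <- ltr_hmm(matrix(c(3, 3, 0, 0, -3, -3), 3, 2, byrow = TRUE),
               vars = 0.5, label = "b")
  hits <- vapply(1:40, function(s) {
    obs <- simulate_hmm(a, 25, seed = s)$obs
    classify_hmm(list(a, b), obs)$label == "a"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # identical models tie to the first, equal scores
  a2 <- a; a2$label <- "a2"
  obs <- simulate_hmm(a, 20, seed = 99)$obs
  r <- classify_hmm(list(a, a2), obs)
  expect_equal(r$label, "a")
  expect_equal(unname(r$scores[1]), unname(r$scores[2]))
  expect_error(classify_hmm(list(a), obs), "at least 2")
})

test_that("HMM JSON serialization round-trips exactly", {
  m <- init_hmm(list(matrix(rnorm(200), 50, 4)), 5L, 2L, seed = 8,
                label = "howling")
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_equal(m2$means, m$means)
  expect_equal(m2$covars, m$covars)
  expect_equal(m2$trans, m$trans)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$label, "howling")
})
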