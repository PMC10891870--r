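test_that("forward pass: zero net is uniform, rows always normalize", {
  p0 <- dnn_init(c(10, 8, 25), seed = 1)
  for (l in seq_along(p0$layers)) {
    p0$layers[[l]]$W[] <- 0
    p0$layers[[l]]$b[] <- 0
  }
  X <- matrix(rnorm(50), 5, 10)
  post <- dnn_posteriors(p0, X)
  expect_equal(post, matrix(1 / 25, 5, 25))
  p <- dnn_init(c(10, 8, 25), seed = 2)
  post2 <- dnn_posteriors(p, X)
  expect_equal(rowSums(post2), rep(1, 5), tolerance = 1e-12)
  expect_true(all(post2 > 0 & post2 < 1))
  expect_error(dnn_posteriors(p, matrix(NaN, 1, 10)), "non-finite")
})

test_that("a hand-built single-unit net reproduces the pencil softmax", {
  # input 1 -> hidden 1 (ReLU) -> output 2 (softmax)
  p <- structure(list(layers = list(
    list(W = matrix(2), b = 0.5),
    list(W = matrix(c(1, -1), 1, 2), b = c(0, 0.25))),
    sizes = c(1L, 1L, 2L)), class = "dnn_params")
  # x = 1: z1 = 2.5, relu = 2.5, logits = (2.5, -2.25)
  post <- dnn_posteriors(p, matrix(1))
  expect_equal(as.numeric(post),
               exp(c(2.5, -2.25)) / sum(exp(c(2.5, -2.25))))
  # x = -1: z1 = -1.5, relu = 0, logits = (0, 0.25)
  post2 <- dnn_posteriors(p, matrix(-1))
  expect_equal(as.numeric(post2),
               exp(c(0, 0.25)) / sum(exp(c(0, 0.25))))
})

test_that("cross-entropy matches closed forms", {
  expect_equal(cross_entropy(matrix(c(1, 0), 1), 1L), 0)
  unif <- matrix(1 / 25, 4, 25)
  expect_equal(cross_entropy(unif, c(1L, 5L, 20L, 25L)), log(25))
  p <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(cross_entropy(p, c(1L, 2L)), -(log(0.7) + log(0.8)) / 2)
})

test_that("backprop matches central finite differences everywhere", {
  set.seed(6)
  p <- dnn_init(c(6, 4, 3, 2), seed = 6)
  # nonzero biases keep every pre-activation away from the ReLU kink,
  # where central differences and the subgradient legitimately disagree
  for (l in seq_along(p$layers))
    p$layers[[l]]$b <- rnorm(length(p$layers[[l]]$b), sd = 0.3)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- sample(1:2, 8, replace = TRUE)
  g <- dnn_gradients(p, X, y)
  e <- 1e-5
  for (l in seq_along(p$layers)) {
    W <- p$layers[[l]]$W
    for (idx in seq_len(length(W))) {
      p1 <- p; p1$layers[[l]]$W[idx] <- W[idx] + e
      p2 <- p; p2$layers[[l]]$W[idx] <- W[idx] - e
      fd <- (cross_entropy(dnn_posteriors(p1, X), y) -
             cross_entropy(dnn_posteriors(p2, X), y)) / (2 * e)
      expect_equal(g[[l]]$W[idx], fd, tolerance = 1e-5)
    }
    for (idx in seq_along(p$layers[[l]]$b)) {
      p1 <- p; p1$layers[[l]]$b[idx] <- p$layers[[l]]$b[idx] + e
      p2 <- p; p2$layers[[l]]$b[idx] <- p$layers[[l]]$b[idx] - e
      fd <- (cross_entropy(dnn_posteriors(p1, X), y) -
             cross_entropy(dnn_posteriors(p2, X), y)) / (2 * e)
      expect_equal(g[[l]]$b[idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("gradients respect zero inputs and batch duplication", {
  p <- dnn_init(c(4, 3, 2), seed = 3)
  g0 <- dnn_gradients(p, matrix(0, 5, 4), rep(1L, 5))
  expect_true(all(g0[[1]]$W == 0))
  expect_false(all(g0[[2]]$b == 0))
  set.seed(8)
  X <- matrix(rnorm(12), 3, 4)
  y <- c(1L, 2L, 1L)
  g1 <- dnn_gradients(p, X, y)
  g2 <- dnn_gradients(p, rbind(X, X), c(y, y))
  for (l in 1:2) {
    expect_equal(g2[[l]]$W, g1[[l]]$W, tolerance = 1e-12)
    expect_equal(g2[[l]]$b, g1[[l]]$b, tolerance = 1e-12)
  }
})

test_that("training separates separable classes and is deterministic", {
  set.seed(10)
  X <- rbind(matrix(rnorm(200, 2), 100, 2), matrix(rnorm(200, -2), 100, 2))
  y <- rep(1:2, each = 100)
  fit <- train_dnn(X, y, hidden = c(16L), epochs = 8L, batch_size = 20L,
                   seed = 7)
  acc <- mean(max.col(dnn_posteriors(fit$params, X), "first") == y)
  expect_gte(acc, 0.99)
  expect_true(all(diff(fit$history$train_loss[1:3]) < 0))
  fit2 <- train_dnn(X, y, hidden = c(16L), epochs = 8L, batch_size = 20L,
                    seed = 7)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("shuffled labels train to chance-level validation accuracy", {
  set.seed(13)
  X <- matrix(rnorm(400 * 4), 400, 4)
  y <- sample(1:4, 400, replace = TRUE)  # labels carry no signal
  fit <- train_dnn(X, y, hidden = c(8L), epochs = 5L, batch_size = 50L,
                   val_fraction = 0.2, seed = 5)
  va <- tail(fit$history$val_acc, 1)
  # chance is 0.25; allow a wide binomial band on ~80 validation points
  expect_lt(abs(va - 0.25), 0.18)
})

test_that("network parameters survive a JSON round trip", {
  p <- dnn_init(c(7, 5, 3), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_dnn(p, path)
  p2 <- read_dnn(path)
  expect_equal(p2$sizes, p$sizes)
  for (l in seq_along(p$layers)) {
    expect_equal(p2$layers[[l]]$W, p$layers[[l]]$W)
    expect_equal(p2$layers[[l]]$b, p$layers[[l]]$b)
  }
})
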