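#' Initialize a feed-forward network
#'
#' He-normal weight initialization (suited to ReLU stacks), zero biases.
#' The default acoustic-model architecture maps 273-d spliced features
#' through three 128-unit ReLU hidden layers to a softmax over all
#' class-state units (25 for 5 classes x 5 states).
#'
#' @param layer_sizes integer vector of layer widths, input first, output
#'   last (e.g. `c(273, 128, 128, 128, 25)`).
#' @param seed RNG seed.
#' @return A list of class `dnn_params` with a `layers` list of
#'   `(W, b)` pairs.
#' @export
dnn_init <- function(layer_sizes, seed = 1L) {
  L <- length(layer_sizes) - 1L
  layers <- vector("list", L)
  with_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      layers[[l]] <- list(
        W = matrix(rnorm(fan_in * layer_sizes[l + 1L], 0,
                         sqrt(2 / fan_in)),
                   fan_in, layer_sizes[l + 1L]),
        b = numeric(layer_sizes[l + 1L]))
    }
  })
  structure(list(layers = layers, sizes = layer_sizes), class = "dnn_params")
}

# forward pass keeping intermediate activations (rows = examples)
dnn_forward_full <- function(params, X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite input to network")
  if (ncol(X) != params$sizes[1L])
    stop("input width ", ncol(X), " does not match network input ",
         params$sizes[1L])
  L <- length(params$layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% params$layers[[l]]$W, 2L, params$layers[[l]]$b, `+`)
    a <- if (l < L) pmax(z, 0) else softmax_rows(z)
    acts[[l + 1L]] <- a
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Network forward pass
#'
#' Hidden layers apply ReLU, the output layer a numerically stable softmax
#' (max subtraction); each output row sums to one.
#'
#' @param params a `dnn_params`.
#' @param X batch matrix, one example per row.
#' @return Matrix of per-row posterior probabilities.
#' @export
dnn_posteriors <- function(params, X) {
  acts <- dnn_forward_full(params, X)
  acts[[length(acts)]]
}

#' Mean cross-entropy loss
#'
#' `-mean(log(posterior at target))` with a probability floor of 1e-12.
#'
#' @param posteriors matrix of row posteriors.
#' @param targets integer targets, 1-based column indices.
#' @return Scalar loss.
#' @export
cross_entropy <- function(posteriors, targets) {
  p <- posteriors[cbind(seq_len(nrow(posteriors)), as.integer(targets))]
  -mean(log(pmax(p, 1e-12)))
}

#' Backpropagation gradients
#'
#' Exact gradients of the mean cross-entropy with respect to every weight
#' matrix and bias vector, using the fused softmax + cross-entropy delta
#' at the output and the ReLU mask through the hidden layers.
#'
#' @param params a `dnn_params`.
#' @param X batch matrix.
#' @param targets 1-based integer targets.
#' @return A list of `(W, b)` gradient pairs matching `params$layers`.
#' @export
dnn_gradients <- function(params, X, targets) {
  acts <- dnn_forward_full(params, X)
  L <- length(params$layers)
  M <- nrow(acts[[1L]])
  delta <- acts[[L + 1L]]
  delta[cbind(seq_len(M), as.integer(targets))] <-
    delta[cbind(seq_len(M), as.integer(targets))] - 1
  delta <- delta / M
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(params$layers[[l]]$W)) * (acts[[l]] > 0)
  }
  grads
}

#' Train the acoustic network
#'
#' Mini-batch Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) on the mean
#' cross-entropy, with a stratified validation split, per-epoch shuffling,
#' early stopping on validation loss, a relative training-loss tolerance,
#' and caps on both epochs and optimizer steps per epoch.  Returns the
#' parameters with the best validation loss.
#'
#' @param X `M x D` matrix of (spliced) input frames.
#' @param y 1-based integer unit targets of length `M`.
#' @param n_out number of output units (default `max(y)`).
#' @param hidden hidden-layer widths (default `c(128, 128, 128)`).
#' @param learning_rate Adam step size (default 0.003).
#' @param batch_size mini-batch size (default 100).
#' @param epochs passes over the data (default 10).
#' @param max_steps_per_epoch optimizer-step cap per epoch (default 200).
#' @param tol relative training-loss change for convergence (default 1e-6).
#' @param val_fraction stratified validation fraction (default 0.1).
#' @param patience validation checks without improvement before stopping
#'   (default 3).
#' @param seed RNG seed controlling init, split and shuffling.
#' @return A list with `params` (best-validation `dnn_params`) and
#'   `history` (per-epoch data.frame: train/validation loss and accuracy).
#' @export
train_dnn <- function(X, y, n_out = max(y), hidden = c(128L, 128L, 128L),
                      learning_rate = 0.003, batch_size = 100L,
                      epochs = 10L, max_steps_per_epoch = 200L, tol = 1e-6,
                      val_fraction = 0.1, patience = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  M <- nrow(X)
  if (length(unique(y)) < 2L) stop("need at least 2 target classes")

  # stratified validation split
  val_idx <- integer(0)
  with_seed(seed + 1L, {
    for (u in unique(y)) {
      iu <- which(y == u)
      n_val <- floor(length(iu) * val_fraction)
      if (n_val >= length(iu)) n_val <- length(iu) - 1L
      if (n_val > 0L) val_idx <- c(val_idx, sample(iu, n_val))
    }
  })
  tr_idx <- setdiff(seq_len(M), val_idx)
  has_val <- length(val_idx) > 0L

  params <- dnn_init(c(ncol(X), hidden, n_out), seed)
  L <- length(params$layers)
  mom <- lapply(params$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = params)
  bad_checks <- 0L
  hist_rows <- list()
  prev_train_loss <- NA_real_

  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 100L + ep, sample(tr_idx))
    n_steps <- min(max_steps_per_epoch, ceiling(length(ord) / batch_size))
    for (s in seq_len(n_steps)) {
      lo <- (s - 1L) * batch_size + 1L
      hi <- min(s * batch_size, length(ord))
      bi <- ord[lo:hi]
      g <- dnn_gradients(params, X[bi, , drop = FALSE], y[bi])
      step <- step + 1L
      for (l in seq_len(L)) {
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * g[[l]]$W
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * g[[l]]$W^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * g[[l]]$b
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * g[[l]]$b^2
        mh <- mom[[l]]$mW / (1 - b1^step)
        vh <- mom[[l]]$vW / (1 - b2^step)
        params$layers[[l]]$W <- params$layers[[l]]$W -
          learning_rate * mh / (sqrt(vh) + eps)
        mhb <- mom[[l]]$mb / (1 - b1^step)
        vhb <- mom[[l]]$vb / (1 - b2^step)
        params$layers[[l]]$b <- params$layers[[l]]$b -
          learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
    tr_post <- dnn_posteriors(params, X[tr_idx, , drop = FALSE])
    tr_loss <- cross_entropy(tr_post, y[tr_idx])
    if (!is.finite(tr_loss)) stop("training diverged (non-finite loss)")
    tr_acc <- mean(max.col(tr_post, "first") == y[tr_idx])
    if (has_val) {
      va_post <- dnn_posteriors(params, X[val_idx, , drop = FALSE])
      va_loss <- cross_entropy(va_post, y[val_idx])
      va_acc <- mean(max.col(va_post, "first") == y[val_idx])
    } else {
      va_loss <- tr_loss; va_acc <- tr_acc
    }
    hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss,
                                  train_acc = tr_acc, val_loss = va_loss,
                                  val_acc = va_acc)
    if (va_loss < best$loss - 1e-12) {
      best <- list(loss = va_loss, params = params)
      bad_checks <- 0L
    } else {
      bad_checks <- bad_checks + 1L
      if (bad_checks >= patience) break
    }
    if (!is.na(prev_train_loss)) {
      rel <- abs(prev_train_loss - tr_loss) / (abs(prev_train_loss) + eps)
      if (rel < tol) break
    }
    prev_train_loss <- tr_loss
  }
  list(params = best$params, history = do.call(rbind, hist_rows))
}

#' Serialize network parameters to JSON
#' @param params a `dnn_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dnn <- function(params, path) {
  obj <- list(format = "pigvoc-dnn-1", sizes = params$sizes,
              layers = lapply(params$layers, function(l)
                list(W = as.vector(l$W), b = l$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dnn
#' @export
read_dnn <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "pigvoc-dnn-1")) stop("unrecognized model file")
  sizes <- as.integer(o$sizes)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers))
    layers[[l]] <- list(W = matrix(o$layers$W[[l]], sizes[l], sizes[l + 1L]),
                        b = as.numeric(o$layers$b[[l]]))
  structure(list(layers = layers, sizes = sizes), class = "dnn_params")
}

#' Plot a training history
#' @param history data.frame from [train_dnn()].
#' @param ... passed to [graphics::plot].
#' @export
plot_training_history <- function(history, ...) {
  plot(history$epoch, history$train_loss, type = "b", xlab = "epoch",
       ylab = "cross-entropy loss",
       ylim = range(c(history$train_loss, history$val_loss)), ...)
  lines(history$epoch, history$val_loss, type = "b", col = "red")
  legend("topright", c("train", "validation"), col = c("black", "red"),
         lty = 1, bty = "n")
  invisible(history)
}
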