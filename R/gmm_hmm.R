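# log(sum(exp(v))) along rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  ifelse(is.finite(mx), mx + log(rowSums(exp(m - mx))), -Inf)
}

#' Construct a left-to-right class HMM
#'
#' One hidden Markov model per vocalization class: initial distribution
#' fixed at `[1, 0, ..., 0]` (decoding must start in the first state),
#' upper-bidiagonal transitions (each state self-loops or advances; the
#' last state is absorbing), and per-state diagonal-covariance Gaussian
#' mixture emissions.
#'
#' @param means `N x K x D` array of component means.
#' @param covars `N x K x D` array of diagonal variances (floored).
#' @param weights `N x K` matrix of mixture weights (rows sum to 1).
#' @param trans `N x N` row-stochastic transition matrix; must be
#'   upper-bidiagonal.
#' @param label class label string.
#' @return An object of class `class_hmm`.
#' @export
class_hmm <- function(means, covars, weights, trans, label = "") {
  N <- dim(means)[1]; K <- dim(means)[2]; D <- dim(means)[3]
  stopifnot(all(dim(covars) == dim(means)),
            nrow(weights) == N, ncol(weights) == K,
            nrow(trans) == N, ncol(trans) == N)
  if (any(abs(rowSums(weights) - 1) > 1e-8)) stop("mixture weights must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stop("transition rows must sum to 1")
  bad <- trans
  bad[cbind(seq_len(N), seq_len(N))] <- 0
  if (N > 1L) bad[cbind(seq_len(N - 1L), 2:N)] <- 0
  if (any(bad != 0)) stop("transitions must be left-to-right (self or next)")
  if (any(covars <= 0)) stop("variances must be positive")
  structure(list(n_states = N, n_mix = K, dim = D,
                 pi = c(1, numeric(N - 1L)), trans = trans,
                 weights = weights, means = means, covars = covars,
                 label = label),
            class = "class_hmm")
}

#' @export
print.class_hmm <- function(x, ...) {
  cat(sprintf("<class_hmm> '%s': %d states x %d components, dim %d\n",
              x$label, x$n_states, x$n_mix, x$dim))
  invisible(x)
}

# per-component log densities: returns list(comp = T x N x K array,
# state = T x N matrix of mixture log-densities)
gmm_log_densities <- function(model, obs) {
  obs <- as.matrix(obs)
  T_ <- nrow(obs); N <- model$n_states; K <- model$n_mix; D <- model$dim
  if (ncol(obs) != D) stop("observation dimension ", ncol(obs),
                           " does not match model dimension ", D)
  comp <- array(-Inf, c(T_, N, K))
  const <- -0.5 * D * log(2 * pi)
  for (j in seq_len(N)) for (k in seq_len(K)) {
    mu <- model$means[j, k, ]
    v <- model$covars[j, k, ]
    quad <- colSums((t(obs) - mu)^2 / v)
    lw <- if (model$weights[j, k] > 0) log(model$weights[j, k]) else -Inf
    comp[, j, k] <- lw + const - 0.5 * sum(log(v)) - 0.5 * quad
  }
  state <- matrix(0, T_, N)
  for (j in seq_len(N))
    state[, j] <- row_logsumexp(matrix(comp[, j, ], T_, K))
  list(comp = comp, state = state)
}

#' Initialize a class HMM from training features
#'
#' Each training sequence is divided into `n_states` equal-duration
#' contiguous blocks; state `j`'s mixture is initialized from the pooled
#' frames of block `j` across sequences (k-means for the component means,
#' per-cluster weights and floored variances).  Transitions start at 0.5
#' self-loop / 0.5 advance, last state absorbing.
#'
#' @param feats_list list of `T x D` feature matrices for one class.
#' @param n_states states `N` (default 5).
#' @param n_mix Gaussian components per state `K` (default 4).
#' @param var_floor variance floor (default 1e-3).
#' @param label class label.
#' @param seed RNG seed for k-means.
#' @return A [class_hmm].
#' @export
init_hmm <- function(feats_list, n_states = 5L, n_mix = 4L, var_floor = 1e-3,
                     label = "", seed = 1L) {
  if (!is.list(feats_list)) feats_list <- list(feats_list)
  ok <- vapply(feats_list, nrow, integer(1)) >= n_states
  if (any(!ok))
    warning(sum(!ok), " sequence(s) shorter than ", n_states,
            " frames skipped during initialization")
  feats_list <- feats_list[ok]
  if (!length(feats_list)) stop("no training sequence has at least ",
                                n_states, " frames")
  D <- ncol(feats_list[[1L]])
  pooled <- vector("list", n_states)
  for (f in feats_list) {
    T_ <- nrow(f)
    bounds <- floor(seq(0, T_, length.out = n_states + 1L))
    for (j in seq_len(n_states))
      pooled[[j]] <- rbind(pooled[[j]],
                           f[(bounds[j] + 1L):bounds[j + 1L], , drop = FALSE])
  }
  means <- array(0, c(n_states, n_mix, D))
  covars <- array(1, c(n_states, n_mix, D))
  weights <- matrix(1 / n_mix, n_states, n_mix)
  # ML (1/n) variances so pooled statistics are invariant to duplicated
  # sequences
  ml_var <- function(X) colMeans(sweep(X, 2L, colMeans(X))^2)
  glob_var <- pmax(ml_var(do.call(rbind, pooled)), var_floor)
  with_seed(seed, {
    for (j in seq_len(n_states)) {
      X <- pooled[[j]]
      if (n_mix == 1L) {
        means[j, 1L, ] <- colMeans(X)
        covars[j, 1L, ] <- pmax(ml_var(X), var_floor)
        next
      }
      ku <- min(n_mix, nrow(unique(X)))
      km <- suppressWarnings(kmeans(X, centers = ku, nstart = 3L,
                                    iter.max = 30L))
      for (k in seq_len(n_mix)) {
        kk <- ((k - 1L) %% ku) + 1L
        sel <- km$cluster == kk
        means[j, k, ] <- km$centers[kk, ]
        covars[j, k, ] <- if (sum(sel) > 1L)
          pmax(ml_var(X[sel, , drop = FALSE]), var_floor)
        else glob_var
        weights[j, k] <- sum(sel) / nrow(X)
      }
      weights[j, ] <- weights[j, ] / sum(weights[j, ])
    }
  })
  trans <- diag(0.5, n_states)
  if (n_states > 1L) {
    trans[cbind(seq_len(n_states - 1L), 2:n_states)] <- 0.5
  }
  trans[n_states, n_states] <- 1
  class_hmm(means, covars, weights, trans, label)
}

#' Forward-backward statistics for one observation sequence
#'
#' Log-domain forward and backward recursions plus the EM posteriors:
#' state occupancies `gamma[t, j]`, per-component occupancies
#' `gamma_mix[t, j, k]` (summing over components recovers `gamma`), and
#' transition pair posteriors `xi[t, i, j]`.
#'
#' @param model a [class_hmm].
#' @param obs `T x D` feature matrix.
#' @return A list of class `hmm_trellis` with `log_alpha`, `log_beta`,
#'   `log_likelihood`, `gamma`, `gamma_mix`, `xi`.
#' @export
forward_backward <- function(model, obs) {
  obs <- as.matrix(obs)
  dens <- gmm_log_densities(model, obs)
  logB <- dens$state
  T_ <- nrow(logB); N <- model$n_states; K <- model$n_mix
  logpi <- log_safe(model$pi)
  logA <- log_safe(model$trans)
  fw <- hmm_forward(logpi, logA, logB)
  lb <- hmm_backward(logA, logB)
  ll <- fw$log_likelihood
  if (!is.finite(ll)) stop("impossible observation sequence (log-likelihood -Inf)")
  la <- fw$log_alpha
  gamma <- exp(la + lb - ll)
  gamma <- gamma / rowSums(gamma)

  # within-state component responsibilities
  gamma_mix <- array(0, c(T_, N, K))
  for (j in seq_len(N)) {
    cj <- matrix(dens$comp[, j, ], T_, K)
    mx <- apply(cj, 1L, max)
    r <- exp(cj - ifelse(is.finite(mx), mx, 0))
    r <- r / pmax(rowSums(r), .Machine$double.xmin)
    gamma_mix[, j, ] <- gamma[, j] * r
  }

  xi <- NULL
  if (T_ > 1L) {
    xi <- array(0, c(T_ - 1L, N, N))
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (!is.finite(logA[i, j])) next
      xi[, i, j] <- exp(la[seq_len(T_ - 1L), i] + logA[i, j] +
                        logB[2:T_, j] + lb[2:T_, j] - ll)
    }
  }
  structure(list(log_alpha = la, log_beta = lb, log_likelihood = ll,
                 gamma = gamma, gamma_mix = gamma_mix, xi = xi),
            class = "hmm_trellis")
}

log_safe <- function(x) ifelse(x > 0, log(x), -Inf)

#' Baum-Welch EM training of a class HMM
#'
#' Multi-sequence expectation-maximization: forward-backward statistics
#' are accumulated over all sequences before any parameter is updated
#' (numerators and denominators summed across sequences and time), so the
#' total log-likelihood is non-decreasing.  The left-to-right zero
#' structure of the transition matrix is preserved — EM cannot resurrect a
#' zero transition.  Components whose total occupancy falls below `1e-8`
#' keep their previous parameters with weights renormalized.
#'
#' @param model an initialized [class_hmm].
#' @param feats_list list of `T x D` feature matrices.
#' @param max_iter maximum EM iterations (default 40).
#' @param tol relative log-likelihood improvement threshold (default 1e-6).
#' @param var_floor variance floor applied at every M-step (default 1e-3).
#' @param verbose print per-iteration log-likelihoods.
#' @return A list with `model` (trained [class_hmm]) and `loglik`
#'   (per-iteration total log-likelihood history).
#' @export
baum_welch <- function(model, feats_list, max_iter = 40L, tol = 1e-6,
                       var_floor = 1e-3, verbose = FALSE) {
  if (!is.list(feats_list)) feats_list <- list(feats_list)
  N <- model$n_states; K <- model$n_mix; D <- model$dim
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    trans_num <- matrix(0, N, N)
    trans_den <- numeric(N)
    occ <- matrix(0, N, K)
    mean_num <- array(0, c(N, K, D))
    sq_num <- array(0, c(N, K, D))
    total_ll <- 0
    for (f in feats_list) {
      f <- as.matrix(f)
      tr <- forward_backward(model, f)
      total_ll <- total_ll + tr$log_likelihood
      T_ <- nrow(f)
      if (!is.null(tr$xi)) {
        trans_num <- trans_num + apply(tr$xi, c(2L, 3L), sum)
        trans_den <- trans_den +
          colSums(tr$gamma[seq_len(T_ - 1L), , drop = FALSE])
      }
      for (j in seq_len(N)) {
        g <- matrix(tr$gamma_mix[, j, ], T_, K)
        occ[j, ] <- occ[j, ] + colSums(g)
        mean_num[j, , ] <- mean_num[j, , ] + t(g) %*% f
        sq_num[j, , ] <- sq_num[j, , ] + t(g) %*% (f^2)
      }
    }
    history <- c(history, total_ll)
    if (verbose) message(sprintf("EM iter %d: loglik %.6f", it, total_ll))

    # M-step
    new_trans <- model$trans
    for (i in seq_len(N)) {
      if (trans_den[i] > 1e-10) {
        row <- trans_num[i, ]
        row[model$trans[i, ] == 0] <- 0
        if (sum(row) > 0) new_trans[i, ] <- row / sum(row)
      }
    }
    new_trans[N, ] <- c(numeric(N - 1L), 1)
    new_w <- model$weights; new_m <- model$means; new_v <- model$covars
    for (j in seq_len(N)) {
      tot <- sum(occ[j, ])
      for (k in seq_len(K)) {
        if (occ[j, k] > 1e-8) {
          mu <- mean_num[j, k, ] / occ[j, k]
          new_m[j, k, ] <- mu
          new_v[j, k, ] <- pmax(sq_num[j, k, ] / occ[j, k] - mu^2, var_floor)
          new_w[j, k] <- occ[j, k] / tot
        } else {
          warning("empty occupancy for state ", j, " component ", k,
                  "; parameters retained")
        }
      }
      new_w[j, ] <- new_w[j, ] / sum(new_w[j, ])
    }
    model <- class_hmm(new_m, new_v, new_w, new_trans, model$label)

    if (it > 1L) {
      rel <- abs(history[it] - history[it - 1L]) /
        (abs(history[it - 1L]) + .Machine$double.eps)
      if (rel < tol) break
    }
  }
  list(model = model, loglik = history)
}

#' Viterbi decoding / forced alignment
#'
#' Max-product dynamic program in the log domain with backtracking; ties
#' break toward the lower state index.  Under the left-to-right topology
#' the returned path is non-decreasing and starts in state 1.
#'
#' @param model a [class_hmm].
#' @param obs `T x D` feature matrix.
#' @return A list of class `hmm_alignment` with `state_ids` (1-based) and
#'   `log_score`.
#' @export
viterbi <- function(model, obs) {
  obs <- as.matrix(obs)
  logB <- gmm_log_densities(model, obs)$state
  res <- hmm_viterbi(log_safe(model$pi), log_safe(model$trans), logB)
  structure(list(state_ids = as.integer(res$path),
                 log_score = res$log_score),
            class = "hmm_alignment")
}

#' Whole-segment classification with per-class HMMs
#'
#' Scores the observation sequence under every model (Viterbi path score
#' by default, forward log-likelihood optionally) and returns the argmax
#' label; ties break to the earlier model.
#'
#' @param models list of [class_hmm] objects with distinct labels.
#' @param obs `T x D` feature matrix.
#' @param method `"viterbi"` (default) or `"forward"`.
#' @return A list with `label` and `scores` (named per-class log-scores).
#'   If all scores are `-Inf` the label is `NA` ("unclassifiable").
#' @export
classify_hmm <- function(models, obs, method = c("viterbi", "forward")) {
  method <- match.arg(method)
  if (length(models) < 2L) stop("need at least 2 class models")
  scores <- vapply(models, function(m) {
    tryCatch(
      if (method == "viterbi") viterbi(m, obs)$log_score
      else forward_backward(m, obs)$log_likelihood,
      error = function(e) -Inf)
  }, numeric(1))
  names(scores) <- vapply(models, function(m) m$label, character(1))
  if (all(!is.finite(scores)))
    return(list(label = NA_character_, scores = scores))
  list(label = names(scores)[which.max(scores)], scores = scores)
}

#' Simulate observation sequences from a class HMM
#'
#' @param model a [class_hmm].
#' @param n_frames sequence length `T`.
#' @param seed RNG seed.
#' @return A list with `obs` (`T x D` matrix) and `states` (true path).
#' @export
simulate_hmm <- function(model, n_frames, seed = 1L) {
  N <- model$n_states; K <- model$n_mix; D <- model$dim
  with_seed(seed, {
    states <- integer(n_frames)
    obs <- matrix(0, n_frames, D)
    s <- sample.int(N, 1L, prob = model$pi)
    for (t in seq_len(n_frames)) {
      states[t] <- s
      k <- sample.int(K, 1L, prob = model$weights[s, ])
      obs[t, ] <- rnorm(D, model$means[s, k, ], sqrt(model$covars[s, k, ]))
      s <- sample.int(N, 1L, prob = model$trans[s, ])
    }
    list(obs = obs, states = states)
  })
}

#' Serialize a class HMM to JSON
#'
#' @param model a [class_hmm].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(model, path) {
  obj <- list(format = "pigvoc-hmm-1", label = model$label,
              n_states = model$n_states, n_mix = model$n_mix,
              dim = model$dim, pi = model$pi, trans = model$trans,
              weights = model$weights,
              means = as.vector(model$means), covars = as.vector(model$covars))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "pigvoc-hmm-1")) stop("unrecognized model file")
  dims <- c(o$n_states, o$n_mix, o$dim)
  class_hmm(array(o$means, dims), array(o$covars, dims),
            matrix(o$weights, o$n_states, o$n_mix),
            matrix(as.numeric(o$trans), o$n_states, o$n_states),
            o$label)
}
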