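#' Estimate class-state unit priors from forced alignments
#'
#' Frame-count priors with add-one smoothing:
#' `p(q) = (count(q) + delta) / (total + delta * n_units)`, so every unit
#' keeps positive mass and the posterior-to-likelihood conversion never
#' divides by zero.
#'
#' @param unit_ids integer vector (or list of vectors) of 1-based unit
#'   indices from forced alignments of the training set.
#' @param n_units total number of class-state units.
#' @param delta smoothing count (default 1).
#' @return Numeric prior vector of length `n_units`, summing to 1.
#' @export
estimate_state_priors <- function(unit_ids, n_units, delta = 1) {
  if (is.list(unit_ids)) unit_ids <- unlist(unit_ids)
  if (!length(unit_ids)) stop("no aligned frames supplied")
  counts <- tabulate(as.integer(unit_ids), nbins = n_units)
  (counts + delta) / (sum(counts) + delta * n_units)
}

#' Map (class, state) to a DNN output unit
#'
#' Class-major indexing: unit = `(class - 1) * n_states + state`.
#'
#' @param class_idx 1-based class index.
#' @param state_idx 1-based state index.
#' @param n_states states per class.
#' @return 1-based unit index.
#' @export
unit_index <- function(class_idx, state_idx, n_states) {
  (class_idx - 1L) * n_states + state_idx
}

#' Assemble a hybrid DNN-HMM model
#'
#' Combines the trained network, the smoothed unit priors and the HMM
#' topologies (initial distributions and transition matrices) of the
#' per-class GMM-HMMs whose alignments supervised the network.
#'
#' @param dnn a `dnn_params` network over the class-state units.
#' @param priors unit prior vector (sums to 1, all positive).
#' @param hmms list of trained [class_hmm] objects, in unit-map order.
#' @return A list of class `hybrid_model`.
#' @export
hybrid_model <- function(dnn, priors, hmms) {
  n_states <- hmms[[1L]]$n_states
  n_units <- length(hmms) * n_states
  stopifnot(length(priors) == n_units, all(priors > 0),
            abs(sum(priors) - 1) < 1e-8,
            dnn$sizes[length(dnn$sizes)] == n_units)
  structure(list(dnn = dnn, priors = priors,
                 labels = vapply(hmms, function(m) m$label, character(1)),
                 n_states = n_states,
                 topologies = lapply(hmms, function(m)
                   list(pi = m$pi, trans = m$trans))),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> %d classes x %d states; DNN %s\n",
              length(x$labels), x$n_states,
              paste(x$dnn$sizes, collapse = "-")))
  invisible(x)
}

#' Prior-scaled frame log-likelihoods
#'
#' Converts DNN posteriors to scaled log-likelihoods
#' `log p(q|x_t) - log p(q)`; the frame evidence `p(x_t)` is dropped as a
#' class-independent per-frame constant that cannot affect decoding.
#'
#' @param model a `hybrid_model`.
#' @param spliced `T x 273` spliced feature matrix.
#' @param posteriors optional precomputed `T x n_units` posterior matrix
#'   (bypasses the network; used for cross-checks).
#' @return A `T x n_units` matrix of scaled log-likelihoods.
#' @export
scaled_log_likelihoods <- function(model, spliced, posteriors = NULL) {
  post <- if (is.null(posteriors)) dnn_posteriors(model$dnn, spliced)
          else as.matrix(posteriors)
  log(pmax(post, 1e-12)) -
    matrix(log(model$priors), nrow(post), length(model$priors), byrow = TRUE)
}

#' Hybrid DNN-HMM classification of a segment
#'
#' Each class is decoded in its own left-to-right trellis: Viterbi (the
#' max-approximation of the acoustic score) runs over that class's columns
#' of the scaled log-likelihood matrix with its own initial and transition
#' probabilities.  The label is the argmax class score; ties break to the
#' first class.
#'
#' @param model a `hybrid_model`.
#' @param spliced `T x 273` spliced feature matrix.
#' @param posteriors optional precomputed posterior matrix (see
#'   [scaled_log_likelihoods()]).
#' @return A list with `label`, `scores` (named per-class), and `paths`
#'   (per-class Viterbi state paths).  `label` is `NA` if every score is
#'   `-Inf`.
#' @export
decode_hybrid <- function(model, spliced, posteriors = NULL) {
  sll <- scaled_log_likelihoods(model, spliced, posteriors)
  N <- model$n_states
  scores <- numeric(length(model$labels))
  paths <- vector("list", length(model$labels))
  for (ci in seq_along(model$labels)) {
    cols <- unit_index(ci, seq_len(N), N)
    topo <- model$topologies[[ci]]
    res <- hmm_viterbi(log_safe(topo$pi), log_safe(topo$trans),
                       sll[, cols, drop = FALSE])
    scores[ci] <- res$log_score
    paths[[ci]] <- as.integer(res$path)
  }
  names(scores) <- model$labels
  if (all(!is.finite(scores)))
    return(list(label = NA_character_, scores = scores, paths = paths))
  list(label = model$labels[which.max(scores)], scores = scores,
       paths = paths)
}
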