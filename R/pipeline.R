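#' Train the full recognition system
#'
#' Executes the training flow on the `train` split of a dataset:
#' optional Kalman denoising, optional endpoint detection (the longest
#' detected segment is kept; pre-segmented clips skip this), 39-d MFCC
#' extraction, per-class GMM-HMM initialization and Baum-Welch EM, Viterbi
#' forced alignment of every training clip under its own class model,
#' class-state prior estimation, supervised training of the spliced-input
#' network on the alignment labels, and hybrid model assembly.  With
#' `include_base = TRUE` a single-Gaussian ("Base-HMM", K = 1) model set
#' is trained on the same features for ablation comparisons.
#'
#' @param dataset a `synthetic_dataset`, or a manifest data.frame whose
#'   `path` column points at WAV files.
#' @param config configuration list ([default_config()]).
#' @param denoise run Kalman denoising before feature extraction.
#' @param endpoint run endpoint detection and keep the longest segment.
#' @param include_base also train K = 1 baseline HMMs.
#' @param verbose print per-stage progress.
#' @return A list of class `pigvoc_model`: `hmms`, `base_hmms` (or NULL),
#'   `dnn`, `dnn_history`, `priors`, `hybrid`, `labels`, `config`.
#' @export
run_train <- function(dataset, config = default_config(), denoise = FALSE,
                      endpoint = FALSE, include_base = FALSE,
                      verbose = FALSE) {
  manifest <- dataset_manifest(dataset)
  train_rows <- which(manifest$split == "train")
  if (!length(train_rows)) stop("manifest has no train split")
  labels <- sort(unique(manifest$label))
  for (lab in labels)
    if (!any(manifest$label[train_rows] == lab))
      stop("class '", lab, "' has no training entries")

  say <- function(...) if (verbose) message(sprintf(...))
  say("featurizing %d training clips", length(train_rows))
  t0 <- proc.time()[3]
  feats <- lapply(train_rows, function(i)
    clip_features(dataset, i, config, denoise, endpoint))
  say("  features done in %.1f s", proc.time()[3] - t0)

  cfg_h <- config$gmm_hmm
  hmms <- vector("list", length(labels))
  base_hmms <- if (include_base) vector("list", length(labels)) else NULL
  for (ci in seq_along(labels)) {
    lab <- labels[ci]
    fl <- feats[manifest$label[train_rows] == lab]
    say("training GMM-HMM for '%s' (%d sequences)", lab, length(fl))
    init <- init_hmm(fl, cfg_h$n_states, cfg_h$n_mix, cfg_h$var_floor,
                     label = lab, seed = config$seed + ci)
    hmms[[ci]] <- baum_welch(init, fl, cfg_h$max_iter, cfg_h$tol,
                             cfg_h$var_floor)$model
    if (include_base) {
      init1 <- init_hmm(fl, cfg_h$n_states, 1L, cfg_h$var_floor,
                        label = lab, seed = config$seed + ci)
      base_hmms[[ci]] <- baum_welch(init1, fl, cfg_h$max_iter, cfg_h$tol,
                                    cfg_h$var_floor)$model
    }
  }

  say("forced alignment + DNN training set assembly")
  N <- cfg_h$n_states
  ctx <- config$features$splice
  Xs <- vector("list", length(train_rows))
  ys <- vector("list", length(train_rows))
  for (ii in seq_along(train_rows)) {
    lab <- manifest$label[train_rows[ii]]
    ci <- match(lab, labels)
    ali <- viterbi(hmms[[ci]], feats[[ii]])
    Xs[[ii]] <- splice_frames(feats[[ii]], ctx)
    ys[[ii]] <- unit_index(ci, ali$state_ids, N)
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  priors <- estimate_state_priors(y, length(labels) * N)

  say("training DNN on %d frames", nrow(X))
  cfg_d <- config$dnn
  fit <- train_dnn(X, y, n_out = length(labels) * N, hidden = cfg_d$hidden,
                   learning_rate = cfg_d$learning_rate,
                   batch_size = cfg_d$batch_size, epochs = cfg_d$epochs,
                   max_steps_per_epoch = cfg_d$max_steps_per_epoch,
                   tol = cfg_d$tol, val_fraction = cfg_d$val_fraction,
                   patience = cfg_d$patience, seed = config$seed)

  structure(list(hmms = hmms, base_hmms = base_hmms, dnn = fit$params,
                 dnn_history = fit$history, priors = priors,
                 hybrid = hybrid_model(fit$params, priors, hmms),
                 labels = labels, config = config,
                 n_train_frames = nrow(X),
                 denoise = denoise, endpoint = endpoint),
            class = "pigvoc_model")
}

#' @export
print.pigvoc_model <- function(x, ...) {
  cat(sprintf("<pigvoc_model> %d classes (%s); %d-state GMM-HMMs + DNN %s\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$config$gmm_hmm$n_states,
              paste(x$dnn$sizes, collapse = "-")))
  invisible(x)
}

#' Evaluate trained models on the test split
#'
#' Classifies every test clip with the GMM-HMM set and the hybrid
#' DNN-HMM on identical features (and with the Base-HMM set when
#' present), and returns an [eval_metrics()] report per system plus a
#' side-by-side comparison table of accuracy, macro recall and macro
#' specificity.
#'
#' @param model a `pigvoc_model` from [run_train()].
#' @param dataset the dataset holding the `test` split.
#' @param verbose print progress.
#' @return A list of class `pigvoc_evaluation`: `gmm_hmm`, `dnn_hmm`,
#'   optionally `base_hmm` (each an `eval_report`), `comparison`
#'   (data.frame), and `predictions`.
#' @export
run_evaluate <- function(model, dataset, verbose = FALSE) {
  manifest <- dataset_manifest(dataset)
  test_rows <- which(manifest$split == "test")
  if (!length(test_rows)) stop("manifest has no test split")
  config <- model$config
  ctx <- config$features$splice
  truth <- manifest$label[test_rows]
  pred_g <- character(length(test_rows))
  pred_h <- character(length(test_rows))
  pred_b <- if (!is.null(model$base_hmms)) character(length(test_rows))
            else NULL
  for (ii in seq_along(test_rows)) {
    f <- clip_features(dataset, test_rows[ii], config,
                       model$denoise, model$endpoint)
    pred_g[ii] <- classify_hmm(model$hmms, f)$label
    pred_h[ii] <- decode_hybrid(model$hybrid, splice_frames(f, ctx))$label
    if (!is.null(pred_b)) pred_b[ii] <- classify_hmm(model$base_hmms, f)$label
    if (verbose && ii %% 25L == 0L)
      message(sprintf("  evaluated %d/%d", ii, length(test_rows)))
  }
  rep_g <- eval_metrics(confusion_matrix(truth, pred_g, model$labels))
  rep_h <- eval_metrics(confusion_matrix(truth, pred_h, model$labels))
  rep_b <- if (!is.null(pred_b))
    eval_metrics(confusion_matrix(truth, pred_b, model$labels)) else NULL
  comp <- do.call(rbind, lapply(
    Filter(Negate(is.null),
           list(base_hmm = rep_b, gmm_hmm = rep_g, dnn_hmm = rep_h)),
    function(r) data.frame(accuracy = r$accuracy,
                           macro_recall = r$macro_recall,
                           macro_specificity = r$macro_specificity)))
  comp <- cbind(model = rownames(comp), comp)
  rownames(comp) <- NULL
  structure(list(gmm_hmm = rep_g, dnn_hmm = rep_h, base_hmm = rep_b,
                 comparison = comp,
                 predictions = data.frame(truth = truth, gmm_hmm = pred_g,
                                          dnn_hmm = pred_h)),
            class = "pigvoc_evaluation")
}

#' @export
print.pigvoc_evaluation <- function(x, ...) {
  cat("<pigvoc_evaluation>\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

dataset_manifest <- function(dataset) {
  if (inherits(dataset, "synthetic_dataset")) return(dataset$manifest)
  validate_manifest(as.data.frame(dataset))
}

load_clip <- function(dataset, row) {
  if (inherits(dataset, "synthetic_dataset"))
    return(dataset$clips[[dataset$manifest$clip[row]]]$audio)
  read_wav(dataset$path[row])
}

# shared front end: audio -> (denoise) -> (endpoint) -> 39-d features
clip_features <- function(dataset, row, config, denoise = FALSE,
                          endpoint = FALSE) {
  x <- load_clip(dataset, row)
  if (denoise)
    x <- denoise_signal(x, config$denoise$frame_len_s,
                        config$denoise$ar_order,
                        noise_quantile = config$denoise$noise_quantile)
  if (endpoint) {
    cfg_e <- config$endpoint
    segs <- detect_endpoints(x, endpoint_config(
      frame_len_s = cfg_e$frame_len_s, hop_s = cfg_e$hop_s,
      alpha = cfg_e$alpha, beta = cfg_e$beta,
      min_speech_s = cfg_e$min_speech_s, min_gap_s = cfg_e$min_gap_s,
      noise_floor_s = cfg_e$noise_floor_s, imf_band = cfg_e$imf_band))
    if (nrow(segs)) {
      best <- which.max(segs$end - segs$start)
      x <- extract_segment(x, segs[best, ])
    }
  }
  cfg_f <- config$features
  featurize(x, n_filters = cfg_f$n_filters,
            frame_len_s = cfg_f$frame_len_s, hop_s = cfg_f$hop_s,
            preemphasis = cfg_f$preemphasis)
}

#' Load a trained model set from a directory
#'
#' Reads the per-class HMM JSON files (`hmm_<label>.json`), the network
#' (`dnn.json`) and the hybrid assembly metadata (`hybrid.json`) written
#' by the command-line `train` subcommand, and reassembles a usable
#' `pigvoc_model`.
#'
#' @param dir directory containing the model files.
#' @param config configuration used for feature extraction at
#'   classification time (default [default_config()]).
#' @return A `pigvoc_model` (without Base-HMM ablation models).
#' @export
read_model_dir <- function(dir, config = default_config()) {
  meta <- jsonlite::read_json(file.path(dir, "hybrid.json"),
                              simplifyVector = TRUE)
  labels <- as.character(meta$labels)
  hmms <- lapply(labels, function(lab)
    read_hmm(file.path(dir, paste0("hmm_", lab, ".json"))))
  dnn <- read_dnn(file.path(dir, "dnn.json"))
  priors <- as.numeric(meta$priors)
  structure(list(hmms = hmms, base_hmms = NULL, dnn = dnn,
                 dnn_history = NULL, priors = priors,
                 hybrid = hybrid_model(dnn, priors, hmms),
                 labels = labels, config = config,
                 n_train_frames = NA_integer_,
                 denoise = FALSE, endpoint = FALSE),
            class = "pigvoc_model")
}
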