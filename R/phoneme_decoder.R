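#' Fit per-channel normalization statistics
#'
#' Mean and standard deviation per channel over a reference window, used to
#' z-score features before classification. Constant channels get a floored
#' standard deviation (with a warning) rather than producing NaNs.
#'
#' @param features frames x channels matrix (>= 2 frames).
#' @return object of class `normalizer_stats` with `mean` and `sd`.
#' @export
fit_normalizer <- function(features) {
  if (nrow(features) < 2) stop_config("need at least 2 frames to normalize")
  mu <- colMeans(features)
  sd <- apply(features, 2, stats::sd)
  if (any(sd < 1e-8)) {
    warning("constant channel(s): standard deviation floored", call. = FALSE)
    sd <- pmax(sd, 1e-8)
  }
  structure(list(mean = mu, sd = sd), class = "normalizer_stats")
}

#' @rdname fit_normalizer
#' @param stats a `normalizer_stats`.
#' @return `normalize_features`: the z-scored feature matrix.
#' @export
normalize_features <- function(features, stats) {
  sweep(sweep(features, 2, stats$mean), 2, stats$sd, "/")
}

# Stack each frame with `left` past and `right` future frames
# (edge-replicated), giving the classifier temporal context.
stack_context <- function(features, left = 2L, right = 2L) {
  n <- nrow(features)
  cols <- lapply((-left):right, function(off) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    features[idx, , drop = FALSE]
  })
  do.call(cbind, cols)
}

#' Training configuration for the frame classifier
#'
#' @param learning_rate initial gradient-descent step size.
#' @param epochs full-batch epochs (>= 1).
#' @param weight_decay L2 penalty on the weights.
#' @param momentum heavy-ball momentum coefficient.
#' @param seed integer seed (training is deterministic given it).
#' @param context_left,context_right past/future frames stacked onto each
#'   frame before classification.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.5, epochs = 40L,
                            weight_decay = 1e-4, momentum = 0.9,
                            seed = 1L, context_left = 2L, context_right = 2L) {
  if (epochs < 1) stop_config("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, momentum = momentum,
                 seed = as.integer(seed),
                 context_left = as.integer(context_left),
                 context_right = as.integer(context_right)),
            class = "training_config")
}

# Full-batch softmax-regression optimizer with heavy-ball momentum and an
# automatic step-size backoff: a step that increases the loss is undone and
# retried at half the rate. Deterministic; convex objective.
softmax_fit <- function(X, y, K, W = NULL, epochs = 40L, lr = 0.5,
                        weight_decay = 1e-4, momentum = 0.9) {
  n <- nrow(X)
  d <- ncol(X)
  if (is.null(W)) W <- matrix(0, d + 1L, K)
  Xb <- cbind(1, X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  vel <- matrix(0, d + 1L, K)
  loss_of <- function(W) {
    Z <- Xb %*% W
    Z <- Z - apply(Z, 1, max)
    lse <- log(rowSums(exp(Z)))
    -mean(Z[cbind(seq_len(n), y)] - lse) +
      0.5 * weight_decay * sum(W[-1, ]^2)
  }
  history <- numeric(0)
  prev_loss <- loss_of(W)
  for (ep in seq_len(epochs)) {
    Z <- Xb %*% W
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P <- P / rowSums(P)
    G <- crossprod(Xb, P - Y) / n
    G[-1, ] <- G[-1, ] + weight_decay * W[-1, ]
    repeat {
      vel_try <- momentum * vel - lr * G
      W_try <- W + vel_try
      new_loss <- loss_of(W_try)
      if (new_loss <= prev_loss + 1e-12 || lr < 1e-6) break
      lr <- lr / 2
      vel <- vel * 0  # reset momentum with the smaller step
    }
    W <- W_try
    vel <- vel_try
    prev_loss <- new_loss
    history <- c(history, new_loss)
  }
  list(W = W, loss_history = history)
}

#' Train the frame-level phoneme classifier
#'
#' Multinomial logistic regression on context-stacked, per-session-normalized
#' frames, minimizing frame-wise cross-entropy. Sessions from different days
#' are pooled, each normalized by its own statistics, which keeps multi-day
#' pooling meaningful under offset drift.
#'
#' @param sessions list of `neural_session` (same channel count/inventory).
#' @param inventory a [phoneme_inventory()].
#' @param config a [training_config()].
#' @return object of class `decoder_model`: `normalizer` (from the most
#'   recent session), `W` (weights incl. bias row), `context_left/right`,
#'   `inventory`, `loss_history`.
#' @export
train_decoder <- function(sessions, inventory = sessions[[1]]$inventory,
                          config = training_config()) {
  if (inherits(sessions, "neural_session")) sessions <- list(sessions)
  n_ch <- ncol(sessions[[1]]$features)
  if (!all(vapply(sessions, function(s) ncol(s$features), 0L) == n_ch)) {
    stop_config("sessions must share the channel count")
  }
  K <- n_phonemes(inventory)
  Xs <- vector("list", length(sessions))
  ys <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    stats <- fit_normalizer(s$features)
    Z <- normalize_features(s$features, stats)
    Xs[[i]] <- stack_context(Z, config$context_left, config$context_right)
    ys[[i]] <- s$frame_labels
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2) stop_config("degenerate task: single-class labels")
  fit <- with_seed(config$seed,
    softmax_fit(X, y, K, epochs = config$epochs, lr = config$learning_rate,
                weight_decay = config$weight_decay,
                momentum = config$momentum))
  last <- sessions[[length(sessions)]]
  structure(list(
    normalizer = fit_normalizer(last$features),
    W = fit$W,
    context_left = config$context_left,
    context_right = config$context_right,
    inventory = inventory,
    loss_history = fit$loss_history,
    config = config
  ), class = "decoder_model")
}

#' Frame-wise phoneme log-probabilities
#'
#' Normalizes and context-stacks the features with the model's statistics and
#' returns the log-softmax output: one row per frame, one column per phoneme,
#' each row log-sum-exp zero.
#'
#' @param model a `decoder_model`.
#' @param features frames x channels matrix.
#' @return frames x phonemes matrix of natural log-probabilities.
#' @export
decode_frames <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$normalizer$mean)) {
    stop_config("channel count mismatch: model %d, features %d",
                length(model$normalizer$mean), ncol(features))
  }
  Z <- normalize_features(features, model$normalizer)
  X <- stack_context(Z, model$context_left, model$context_right)
  S <- cbind(1, X) %*% model$W
  S <- S - apply(S, 1, max)
  S - log(rowSums(exp(S)))
}

#' Frame accuracy of a decoder on a session
#'
#' Fraction of frames whose argmax phoneme matches the ground-truth label.
#'
#' @param model a `decoder_model`.
#' @param session a `neural_session`.
#' @return scalar in \[0, 1\].
#' @export
frame_accuracy <- function(model, session) {
  lp <- decode_frames(model, session$features)
  mean(max.col(lp, ties.method = "first") == session$frame_labels)
}

#' Recalibration configuration
#'
#' @param n_calib_sentences sentences used to recalibrate (default 20).
#' @param mode `"supervised"` (ground-truth frame labels) or
#'   `"pseudo_label"` (labels from aligning the sentence decoder's own output
#'   to the frame probabilities).
#' @param epochs,learning_rate fine-tuning schedule.
#' @param refit_normalizer refit the per-channel statistics on the new day's
#'   data (the main defense against offset drift).
#' @param seed integer seed.
#' @return object of class `recalibration_config`.
#' @export
recalibration_config <- function(n_calib_sentences = 20L,
                                 mode = c("supervised", "pseudo_label"),
                                 epochs = 20L, learning_rate = 0.2,
                                 refit_normalizer = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (n_calib_sentences < 1) stop_config("n_calib_sentences must be >= 1")
  structure(list(n_calib_sentences = as.integer(n_calib_sentences),
                 mode = mode, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 refit_normalizer = isTRUE(refit_normalizer),
                 seed = as.integer(seed)),
            class = "recalibration_config")
}

#' Fine-tune a decoder on a new day's data
#'
#' Returns an updated copy of the model (the input is unchanged): the
#' normalizer is refit on the calibration data and the classifier weights are
#' updated by a few epochs of gradient descent, starting from the current
#' weights. In `"pseudo_label"` mode the frame labels come from force-aligning
#' the sentence decoder's decoded words to the frame probabilities; a
#' `decode_handle` list with `lexicon`, `lm` and `beam_config` must then be
#' supplied.
#'
#' @param model a `decoder_model`.
#' @param session a `neural_session` from the (possibly drifted) day.
#' @param config a [recalibration_config()].
#' @param labels optional explicit frame labels (defaults to the session's
#'   ground truth in supervised mode).
#' @param decode_handle list(lexicon, lm, beam_config) for pseudo-label mode.
#' @return the fine-tuned `decoder_model`.
#' @export
fine_tune <- function(model, session, config = recalibration_config(),
                      labels = NULL, decode_handle = NULL) {
  if (config$epochs == 0L) return(model)
  use <- utils::head(seq_len(nrow(session$spans)), config$n_calib_sentences)
  frames <- unlist(lapply(use, function(i)
    seq(session$spans$start[i], session$spans$end[i])))
  feats <- session$features[frames, , drop = FALSE]
  new_model <- model
  if (config$refit_normalizer) {
    new_model$normalizer <- fit_normalizer(feats)
  }
  y <- if (!is.null(labels)) {
    labels[frames]
  } else if (config$mode == "supervised") {
    session$frame_labels[frames]
  } else {
    if (is.null(decode_handle)) {
      stop_config("pseudo_label mode needs a decode_handle (lexicon, lm, beam_config)")
    }
    pseudo_label_frames(new_model, session, use, decode_handle)
  }
  Z <- normalize_features(feats, new_model$normalizer)
  X <- stack_context(Z, model$context_left, model$context_right)
  fit <- with_seed(config$seed,
    softmax_fit(X, y, ncol(model$W), W = model$W, epochs = config$epochs,
                lr = config$learning_rate,
                weight_decay = model$config$weight_decay %||% 1e-4,
                momentum = model$config$momentum %||% 0.9))
  new_model$W <- fit$W
  new_model$loss_history <- c(model$loss_history, fit$loss_history)
  new_model
}

# Pseudo-labels: decode each calibration sentence with the beam search, then
# force-align the decoded pronunciation to the frame log-probabilities.
pseudo_label_frames <- function(model, session, sentence_idx, handle) {
  unlist(lapply(sentence_idx, function(i) {
    fr <- seq(session$spans$start[i], session$spans$end[i])
    lp <- decode_frames(model, session$features[fr, , drop = FALSE])
    res <- beam_search(lp, handle$lexicon, handle$lm,
                       handle$beam_config %||% beam_config())
    al <- align_words_to_frames(res$words, lp, handle$lexicon,
                                model$inventory)
    al$path
  }))
}

#' Save / load a decoder model
#'
#' Serializes the model (normalizer, classifier weights, metadata) to a
#' single portable JSON file.
#'
#' @param model a `decoder_model`.
#' @param path file path.
#' @export
save_decoder <- function(model, path) {
  obj <- list(
    normalizer = list(mean = model$normalizer$mean, sd = model$normalizer$sd),
    classifier = list(W = as.vector(model$W), dim = dim(model$W)),
    meta = list(context_left = model$context_left,
                context_right = model$context_right,
                inventory = model$inventory$symbols,
                loss_history = model$loss_history)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inv <- phoneme_inventory()
  stopifnot(identical(inv$symbols, as.character(obj$meta$inventory)))
  structure(list(
    normalizer = structure(list(mean = obj$normalizer$mean,
                                sd = obj$normalizer$sd),
                           class = "normalizer_stats"),
    W = matrix(obj$classifier$W, obj$classifier$dim[1], obj$classifier$dim[2]),
    context_left = as.integer(obj$meta$context_left),
    context_right = as.integer(obj$meta$context_right),
    inventory = inv,
    loss_history = obj$meta$loss_history,
    config = training_config()
  ), class = "decoder_model")
}
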