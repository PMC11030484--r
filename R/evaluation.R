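#' Edit-distance error counts
#'
#' @param S,D,I,N substitution, deletion, insertion counts and reference
#'   length.
#' @return object of class `error_counts`.
#' @export
error_counts <- function(S = 0L, D = 0L, I = 0L, N = 0L) {
  stopifnot(S >= 0, D >= 0, I >= 0, N >= 0)
  structure(list(S = as.integer(S), D = as.integer(D), I = as.integer(I),
                 N = as.integer(N)), class = "error_counts")
}

#' Align two token sequences by minimal edit distance
#'
#' Unit-cost Levenshtein alignment; among minimal alignments the backtrace
#' prefers matches, then substitutions, then deletions, then insertions.
#' The error definition mirrors standard phoneme/word error-rate scoring:
#' an error is an insertion, deletion or substitution needed to turn the
#' hypothesis into the reference.
#'
#' @param reference,hypothesis character (or comparable) token vectors;
#'   empty sequences allowed.
#' @param details if `FALSE`, skip building the operation table (faster for
#'   bulk scoring; `counts` is unchanged).
#' @return list with `counts` (an [error_counts()]) and `ops` (data.frame
#'   `op`, `ref`, `hyp`, in reference order; `NULL` when `details = FALSE`).
#' @export
align_sequences <- function(reference, hypothesis, details = TRUE) {
  r <- as.character(reference)
  h <- as.character(hypothesis)
  n <- length(r); m <- length(h)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n > 0 && m > 0) {
    js <- seq_len(m)
    for (i in seq_len(n)) {
      # diagonal/vertical candidates, then resolve the horizontal (insertion)
      # recurrence in closed form: D[i+1,j+1] = j + min over k <= j of
      # (cand[k] - k), including the left edge D[i+1,1] = i.
      cand <- D[i, js] + (r[i] != h)
      up <- D[i, js + 1L] + 1L
      lt <- up < cand
      cand[lt] <- up[lt]
      v <- cummin(cand - js)
      v[v > i] <- i
      D[i + 1L, js + 1L] <- js + v
    }
  }
  # backtrace with fixed tie order: match > substitution > deletion > insertion
  op <- character(n + m)
  refs <- character(n + m)
  hyps <- character(n + m)
  k <- 0L
  i <- n; j <- m
  while (i > 0 || j > 0) {
    k <- k + 1L
    if (i > 0 && j > 0 && r[i] == h[j] && D[i + 1L, j + 1L] == D[i, j]) {
      op[k] <- "match"; refs[k] <- r[i]; hyps[k] <- h[j]
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && j > 0 && r[i] != h[j] &&
               D[i + 1L, j + 1L] == D[i, j] + 1L) {
      op[k] <- "sub"; refs[k] <- r[i]; hyps[k] <- h[j]
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      op[k] <- "del"; refs[k] <- r[i]; hyps[k] <- NA_character_
      i <- i - 1L
    } else {
      op[k] <- "ins"; refs[k] <- NA_character_; hyps[k] <- h[j]
      j <- j - 1L
    }
  }
  idx <- if (k > 0) k:1 else integer(0)
  op <- op[idx]
  counts <- structure(list(S = sum(op == "sub"), D = sum(op == "del"),
                           I = sum(op == "ins"), N = n),
                      class = "error_counts")
  out_ops <- if (details) {
    data.frame(op = op, ref = refs[idx], hyp = hyps[idx],
               stringsAsFactors = FALSE)
  } else NULL
  list(counts = counts, ops = out_ops)
}

#' Micro-averaged error rate
#'
#' Pools counts across sentences before dividing: the ratio of all errors to
#' the total number of reference tokens. May exceed 1.
#'
#' @param counts an `error_counts` or list of them.
#' @return scalar rate.
#' @export
error_rate <- function(counts) {
  if (inherits(counts, "error_counts")) counts <- list(counts)
  S <- sum(vapply(counts, `[[`, 0L, "S"))
  D <- sum(vapply(counts, `[[`, 0L, "D"))
  I <- sum(vapply(counts, `[[`, 0L, "I"))
  N <- sum(vapply(counts, `[[`, 0L, "N"))
  if (N == 0) stop_config("error rate undefined: total reference length is 0")
  (S + D + I) / N
}

#' Percentile-bootstrap confidence interval for an error rate
#'
#' Resamples sentences with replacement, recomputes the micro error rate for
#' each replicate, and takes the percentile interval. Deterministic given the
#' seed.
#'
#' @param counts list of per-sentence `error_counts` (>= 1).
#' @param n_resamples bootstrap replicates (default 10000).
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @return object of class `ci_result`: `point`, `lower`, `upper`, `level`,
#'   `n_resamples`, `seed`.
#' @export
bootstrap_ci <- function(counts, n_resamples = 10000L, level = 0.95,
                         seed = 1L) {
  if (inherits(counts, "error_counts")) counts <- list(counts)
  if (length(counts) == 0) stop_config("bootstrap_ci needs at least 1 sentence")
  stopifnot(level > 0, level < 1)
  e <- vapply(counts, function(x) x$S + x$D + x$I, 0L)
  n <- vapply(counts, `[[`, 0L, "N")
  point <- error_rate(counts)
  S <- length(e)
  rates <- with_seed(seed, {
    out <- numeric(n_resamples)
    chunk <- 2000L
    done <- 0L
    while (done < n_resamples) {
      k <- min(chunk, n_resamples - done)
      idx <- matrix(sample.int(S, k * S, replace = TRUE), k, S)
      out[done + seq_len(k)] <-
        rowSums(matrix(e[idx], k, S)) / rowSums(matrix(n[idx], k, S))
      done <- done + k
    }
    out
  })
  rates <- rates[is.finite(rates)]
  q <- stats::quantile(rates, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  structure(list(point = point, lower = q[1], upper = q[2], level = level,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)), class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%.4f [%.4f, %.4f] (%d%% percentile bootstrap, %d resamples)\n",
              x$point, x$lower, x$upper, round(100 * x$level),
              x$n_resamples))
  invisible(x)
}

#' Phoneme confusion matrix and articulatory-similarity ratio
#'
#' Tallies matches (diagonal) and substitution pairs (off-diagonal) from
#' phoneme-level alignments, and compares the probability that a substituted
#' pair shares manner or place of articulation with the chance level under
#' independent marginal shuffling of the substitution pairs.
#'
#' @param alignments list of [align_sequences()] results (or their `ops`) on
#'   phoneme sequences.
#' @param inventory a [phoneme_inventory()].
#' @return list: `matrix` (phonemes x phonemes counts), `n_substitutions`,
#'   `within_class_ratio` (observed / chance; `NA` with no substitutions).
#' @export
phoneme_confusion <- function(alignments, inventory = phoneme_inventory()) {
  ops <- do.call(rbind, lapply(alignments, function(a) {
    if (!is.null(a$ops)) a$ops else a
  }))
  P <- length(inventory$symbols)
  M <- matrix(0L, P, P, dimnames = list(inventory$symbols, inventory$symbols))
  mt <- ops[ops$op == "match", , drop = FALSE]
  if (nrow(mt)) {
    tt <- table(factor(mt$ref, levels = inventory$symbols))
    diag(M) <- as.integer(tt)
  }
  sb <- ops[ops$op == "sub", , drop = FALSE]
  ratio <- NA_real_
  if (nrow(sb)) {
    for (i in seq_len(nrow(sb))) {
      M[sb$ref[i], sb$hyp[i]] <- M[sb$ref[i], sb$hyp[i]] + 1L
    }
    feats <- articulatory_features()
    ok <- sb$ref %in% feats$phoneme & sb$hyp %in% feats$phoneme
    if (any(ok)) {
      fr <- feats[match(sb$ref[ok], feats$phoneme), ]
      fh <- feats[match(sb$hyp[ok], feats$phoneme), ]
      same <- fr$manner == fh$manner | fr$place == fh$place
      obs <- mean(same)
      # chance: independent draws from the two marginals
      pr <- table(factor(sb$ref[ok], levels = feats$phoneme)) / sum(ok)
      ph <- table(factor(sb$hyp[ok], levels = feats$phoneme)) / sum(ok)
      same_mat <- outer(feats$manner, feats$manner, "==") |
        outer(feats$place, feats$place, "==")
      chance <- as.numeric(t(as.vector(pr)) %*% same_mat %*% as.vector(ph))
      ratio <- if (chance > 0) obs / chance else NA_real_
    }
  }
  list(matrix = M, n_substitutions = nrow(sb), within_class_ratio = ratio)
}

#' Write a confusion matrix as labeled CSV
#' @param confusion a [phoneme_confusion()] result.
#' @param path output file.
#' @export
write_confusion_csv <- function(confusion, path) {
  utils::write.csv(confusion$matrix, path)
  invisible(path)
}

#' Per-word error rate versus training-data frequency
#'
#' For every reference word of the decode results, tallies how often it was
#' decoded wrongly (substituted or deleted) and how often it occurred in the
#' decoder's training corpus (0 = novel word), and reports the Spearman rank
#' correlation between training count and per-word error rate.
#'
#' @param results data.frame with `reference` and `hypothesis` sentence
#'   strings.
#' @param training_corpus character vector of training sentences.
#' @return list: `table` (word, training_count, occurrences, errors,
#'   error_rate), `spearman_rho` (`NA` when error-free).
#' @export
word_error_vs_training_count <- function(results, training_corpus) {
  train_tokens <- unlist(strsplit(tolower(training_corpus), "\\s+"))
  tc <- table(train_tokens)
  occ <- new.env(parent = emptyenv())
  err <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(results))) {
    r <- strsplit(tolower(results$reference[i]), "\\s+")[[1]]
    h <- strsplit(tolower(results$hypothesis[i]), "\\s+")[[1]]
    h <- h[h != ""]
    al <- align_sequences(r, h)
    refops <- al$ops[al$ops$op %in% c("match", "sub", "del"), , drop = FALSE]
    for (k in seq_len(nrow(refops))) {
      w <- refops$ref[k]
      occ[[w]] <- (occ[[w]] %||% 0L) + 1L
      if (refops$op[k] != "match") err[[w]] <- (err[[w]] %||% 0L) + 1L
    }
  }
  words <- sort(ls(occ))
  tab <- data.frame(
    word = words,
    training_count = as.integer(ifelse(is.na(tc[words]), 0L, tc[words])),
    occurrences = vapply(words, function(w) occ[[w]], 0L),
    errors = vapply(words, function(w) err[[w]] %||% 0L, 0L),
    stringsAsFactors = FALSE
  )
  tab$error_rate <- tab$errors / tab$occurrences
  rho <- if (all(tab$errors == 0L) || nrow(tab) < 3) NA_real_ else
    suppressWarnings(stats::cor(tab$training_count, tab$error_rate,
                                method = "spearman"))
  list(table = tab, spearman_rho = rho)
}

#' Words per minute from frame spans
#'
#' @param n_words total words produced.
#' @param n_frames total frames spanned.
#' @param bin_ms frame duration (80).
#' @return words per minute.
#' @export
words_per_minute <- function(n_words, n_frames, bin_ms = 80L) {
  minutes <- n_frames * bin_ms / 60000
  if (minutes <= 0) return(NA_real_)
  n_words / minutes
}

#' Channel-group ablation
#'
#' Retrains the frame decoder on each channel group alone and reports the
#' per-group word error rate on the evaluation session, probing which
#' simulated array carries the most speech information.
#'
#' @param train_sessions list of `neural_session` for decoder training.
#' @param eval_session `neural_session` to decode.
#' @param lexicon,lm decoding constraints.
#' @param groups named list of channel indices (defaults to the session
#'   config's groups).
#' @param train_config a [training_config()].
#' @param beam a [beam_config()].
#' @return data.frame `group`, `n_channels`, `wer`, ordered as given.
#' @export
channel_group_ablation <- function(train_sessions, eval_session, lexicon, lm,
                                   groups = NULL,
                                   train_config = training_config(),
                                   beam = beam_config(beam_width = 16L)) {
  if (inherits(train_sessions, "neural_session")) {
    train_sessions <- list(train_sessions)
  }
  groups <- groups %||% eval_session$config$channel_groups
  out <- data.frame(group = names(groups),
                    n_channels = lengths(groups), wer = NA_real_,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(groups)) {
    ch <- groups[[gi]]
    if (length(ch) == 0) stop_config("group '%s' has zero channels",
                                     names(groups)[gi])
    tr <- lapply(train_sessions, subset_channels, ch)
    ev <- subset_channels(eval_session, ch)
    model <- train_decoder(tr, config = train_config)
    res <- decode_session(model, ev, lexicon, lm, beam)
    out$wer[gi] <- wer(res$reference, res$hypothesis)
  }
  out
}

# Restrict a session to a subset of channels.
subset_channels <- function(session, channels) {
  s <- session
  s$features <- session$features[, channels, drop = FALSE]
  s$config$n_channels <- length(channels)
  s$config$channel_groups <- list(sub = seq_along(channels))
  s
}

#' Micro word error rate between sentence strings
#'
#' @param reference,hypothesis character vectors of sentences.
#' @return pooled error rate.
#' @export
wer <- function(reference, hypothesis) {
  counts <- lapply(seq_along(reference), function(i) {
    r <- strsplit(tolower(reference[i]), "\\s+")[[1]]
    h <- strsplit(tolower(hypothesis[i]), "\\s+")[[1]]
    align_sequences(r[r != ""], h[h != ""])$counts
  })
  error_rate(counts)
}

#' Session-level report
#'
#' Aggregates decode results into the session's reporting currency:
#' micro-averaged word (and optionally phoneme) error rate with percentile
#' bootstrap confidence intervals, speaking rate, and — for conversation
#' logs — the fraction of sentences whose decoding was confirmed correct,
#' with unreported sentences excluded from the self-report breakdown. The
#' per-sentence resampling unit and the pooled-counts aggregation follow the
#' standard error-rate methodology; note that restricting to
#' sentences with known ground truth can inflate or deflate the rate (a
#' selection effect this report flags but does not correct).
#'
#' @param results data.frame with `reference`, `hypothesis`, optionally
#'   `ref_phonemes`, `hyp_phonemes` (space-joined) and `frames`.
#' @param conversation_log optional data.frame with `self_report` in
#'   `c("correct", "incorrect", "none")`.
#' @param n_resamples,level,seed bootstrap parameters.
#' @return object of class `session_report`.
#' @export
session_report <- function(results = NULL, conversation_log = NULL,
                           n_resamples = 10000L, level = 0.95, seed = 1L) {
  rep_out <- list()
  if (!is.null(results) && nrow(results) > 0) {
    wc <- lapply(seq_len(nrow(results)), function(i) {
      r <- strsplit(tolower(results$reference[i]), "\\s+")[[1]]
      h <- strsplit(tolower(results$hypothesis[i]), "\\s+")[[1]]
      align_sequences(r[r != ""], h[h != ""])$counts
    })
    rep_out$n_sentences <- nrow(results)
    rep_out$n_words <- sum(vapply(wc, `[[`, 0L, "N"))
    rep_out$wer <- error_rate(wc)
    rep_out$wer_ci <- bootstrap_ci(wc, n_resamples, level, seed)
    if (!is.null(results$ref_phonemes)) {
      pc <- lapply(seq_len(nrow(results)), function(i) {
        align_sequences(strsplit(results$ref_phonemes[i], "\\s+")[[1]],
                        strsplit(results$hyp_phonemes[i], "\\s+")[[1]])$counts
      })
      rep_out$per <- error_rate(pc)
      rep_out$per_ci <- bootstrap_ci(pc, n_resamples, level, seed + 1L)
    }
    if (!is.null(results$frames)) {
      rep_out$words_per_minute <- words_per_minute(rep_out$n_words,
                                                   sum(results$frames))
    }
  } else {
    rep_out$n_sentences <- 0L
  }
  if (!is.null(conversation_log)) {
    sr <- conversation_log$self_report
    n_total <- length(sr)
    n_correct <- sum(sr == "correct")
    n_incorrect <- sum(sr == "incorrect")
    n_none <- sum(sr == "none")
    rep_out$conversation <- list(
      n_total = n_total,
      n_confirmed_correct = n_correct,
      n_confirmed_incorrect = n_incorrect,
      n_no_report = n_none,
      confirmed_fraction = if (n_total > 0) n_correct / n_total else NA_real_,
      # breakdown among sentences with a self-report (no-reports excluded)
      reported_correct_fraction =
        if (n_correct + n_incorrect > 0) n_correct / (n_correct + n_incorrect)
        else NA_real_
    )
  }
  structure(rep_out, class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  if (!is.null(x$wer)) {
    cat(sprintf("Session: %d sentences, %d words; WER %.2f%% [%.2f%%, %.2f%%]\n",
                x$n_sentences, x$n_words, 100 * x$wer,
                100 * x$wer_ci$lower, 100 * x$wer_ci$upper))
    if (!is.null(x$per)) {
      cat(sprintf("  raw PER %.2f%% [%.2f%%, %.2f%%]\n", 100 * x$per,
                  100 * x$per_ci$lower, 100 * x$per_ci$upper))
    }
    if (!is.null(x$words_per_minute)) {
      cat(sprintf("  %.1f words per minute\n", x$words_per_minute))
    }
  }
  if (!is.null(x$conversation)) {
    cv <- x$conversation
    cat(sprintf("Conversation: %d sentences, %d confirmed correct (%.1f%%), %d no report\n",
                cv$n_total, cv$n_confirmed_correct,
                100 * cv$confirmed_fraction, cv$n_no_report))
  }
  invisible(x)
}
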