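# Shared fixtures: a small inventory-checked lexicon, a reduced 64-channel
# recording geometry (same four named groups), and cached mid-size objects
# so expensive fixtures are built once per test run.

test_inv <- phoneme_inventory()

tiny_lexicon <- function() {
  read_lexicon(c("HI HH AY1", "HIGH HH AY1", "A AH0", "AT AE1 T",
                 "CAT K AE1 T", "BE B IY1", "BEE B IY1", "TEA T IY1"),
               test_inv)
}

small_config <- function(noise_sd = 1.0, ...) {
  session_config(n_channels = 64L,
                 channel_groups = list(v6v = 1:16, `55b` = 17:32,
                                       `4` = 33:48, d6v = 49:64),
                 noise_sd = noise_sd, ...)
}

# uniform log-probability rows over the inventory
uniform_logprobs <- function(n_frames, inv = test_inv) {
  matrix(-log(length(inv$symbols)), n_frames, length(inv$symbols))
}

# one-hot-ish frame log-probabilities spelling a label sequence
one_hot_logprobs <- function(labels, inv = test_inv, lo = -50) {
  lp <- matrix(lo, length(labels), length(inv$symbols))
  lp[cbind(seq_along(labels), phoneme_id(inv, labels))] <- 0
  lp - log(rowSums(exp(lp)))
}

# a detector with hand-set calibration on a single channel: speech
# probability is logistic(bias + gain * smoothed(z^2))
manual_detector <- function(gain = 8, bias = -4, smooth_window = 1L,
                            theta_on = 0.8, theta_off = 0.4) {
  structure(list(
    normalizer = structure(list(mean = 0, sd = 1),
                           class = "normalizer_stats"),
    weights = 1,
    calibration = c(bias, gain),
    smooth_window = as.integer(smooth_window),
    theta_on = theta_on, theta_off = theta_off
  ), class = "speech_detector")
}

.fixtures <- new.env(parent = emptyenv())

# A cached trained small-scale copy-task setup shared by decoder and
# pipeline tests: 64 channels, 50-word lexicon, bigram LM, 40 training
# sentences at default noise.
copy_fixture <- function() {
  if (!is.null(.fixtures$copy)) return(.fixtures$copy)
  lexicon <- lexicon_50()
  vocab <- vocabulary(lexicon)
  config <- small_config()
  tuning <- build_tuning(test_inv, config, seed = 11L)
  lm <- train_ngram(make_corpus(vocab, 400, seed = 12L), order = 2L,
                    vocabulary = vocab)
  train_session <- synthesize_session(make_corpus(vocab, 40, seed = 13L),
                                      lexicon, tuning, config, seed = 14L)
  eval_session <- synthesize_session(make_corpus(vocab, 10, seed = 15L),
                                     lexicon, tuning, config, seed = 16L)
  model <- train_decoder(train_session,
                         config = training_config(epochs = 25L))
  .fixtures$copy <- list(lexicon = lexicon, vocab = vocab, config = config,
                         tuning = tuning, lm = lm,
                         train_session = train_session,
                         eval_session = eval_session, model = model)
  .fixtures$copy
}

# memoized recursive edit distance (independent oracle for alignment tests)
recursive_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j - 1) + (a[i] != b[j]),
             rec(i - 1, j) + 1,
             rec(i, j - 1) + 1)
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# brute-force reference for the hysteresis state machine: for every onset,
# scan forward for the first frame where the probability has been below
# theta_off for `timeout` consecutive frames.
reference_segments <- function(p, theta_on, theta_off, timeout) {
  events <- list()
  t <- 1L
  n <- length(p)
  while (t <= n) {
    if (p[t] >= theta_on) {
      start <- t
      last_active <- t
      fin <- NA_integer_
      t2 <- t + 1L
      while (t2 <= n) {
        if (p[t2] >= theta_off) last_active <- t2
        if (t2 - last_active >= timeout) { fin <- t2; break }
        t2 <- t2 + 1L
      }
      if (is.na(fin)) {
        events[[length(events) + 1L]] <- c(start, last_active, n, 0L)
        break
      }
      events[[length(events) + 1L]] <- c(start, last_active, fin, 1L)
      t <- fin + 1L
    } else {
      t <- t + 1L
    }
  }
  if (!length(events)) {
    return(data.frame(start = integer(0), end = integer(0),
                      finalized_at = integer(0), timeout = integer(0)))
  }
  m <- do.call(rbind, events)
  data.frame(start = m[, 1], end = m[, 2], finalized_at = m[, 3],
             timeout = m[, 4])
}
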