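#' Session configuration for the synthetic cortex
#'
#' Describes the recording geometry and timing of a simulated session:
#' 256 channels in four named 64-channel groups (labels follow the implanted
#' array areas; they are labels only), 80 ms feature bins, and the timing and
#' noise of attempted speech.
#'
#' @param n_channels number of recorded channels.
#' @param channel_groups named list partitioning `1:n_channels` into groups.
#' @param bin_ms frame duration in milliseconds; fixed at 80.
#' @param frames_per_phoneme_mean expected frames an attempted phoneme
#'   occupies (mean of the geometric-like duration model, minimum 1 frame).
#'   The default of 4 frames (320 ms) gives speaking rates around 30 words
#'   per minute.
#' @param sil_frames silence frames at sentence boundaries and between words.
#' @param noise_sd standard deviation of the additive Gaussian rate noise.
#' @param jitter_durations if `FALSE`, every phoneme lasts exactly
#'   `round(frames_per_phoneme_mean)` frames (useful for exact tests).
#' @param seed default integer seed for generators that are not passed one.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_channels = 256L,
                           channel_groups = NULL,
                           bin_ms = 80L,
                           frames_per_phoneme_mean = 4,
                           sil_frames = 3L,
                           noise_sd = 1.5,
                           jitter_durations = TRUE,
                           seed = 1L) {
  if (bin_ms != 80L) stop_config("bin_ms is fixed at 80 ms")
  if (frames_per_phoneme_mean < 1) {
    stop_config("frames_per_phoneme_mean must be >= 1")
  }
  if (is.null(channel_groups)) {
    if (n_channels %% 4 != 0) {
      stop_config("default channel grouping needs n_channels divisible by 4")
    }
    per <- n_channels / 4
    channel_groups <- list(
      v6v = seq_len(per),
      `55b` = seq_len(per) + per,
      `4` = seq_len(per) + 2 * per,
      d6v = seq_len(per) + 3 * per
    )
  }
  all_ch <- sort(unlist(channel_groups, use.names = FALSE))
  if (!identical(as.integer(all_ch), seq_len(n_channels))) {
    stop_config("channel_groups must partition 1:n_channels")
  }
  structure(list(
    n_channels = as.integer(n_channels),
    channel_groups = lapply(channel_groups, as.integer),
    bin_ms = 80L,
    frames_per_phoneme_mean = frames_per_phoneme_mean,
    sil_frames = as.integer(sil_frames),
    noise_sd = noise_sd,
    jitter_durations = isTRUE(jitter_durations),
    seed = as.integer(seed)
  ), class = "session_config")
}

#' Default array informativeness
#'
#' Per-group multipliers on tuning gain realizing the empirical ordering of
#' array informativeness for speech decoding: ventral 6v strongest, then 55b,
#' then area 4, dorsal 6v weakest.
#'
#' @return named numeric vector.
#' @export
default_informativeness <- function() {
  c(v6v = 1, `55b` = 0.6, `4` = 0.5, d6v = 0.2)
}

#' Build a ground-truth tuning model
#'
#' Draws the generative mapping from phonemes to channel rates: a strictly
#' positive per-channel baseline and a channels x phonemes gain matrix whose
#' rows are Gaussian draws scaled by the channel's group informativeness.
#' The `SIL` column is zero: silence is baseline activity.
#'
#' @param inventory a [phoneme_inventory()].
#' @param config a [session_config()].
#' @param informativeness named per-group gain multipliers; names must match
#'   `config$channel_groups`.
#' @param seed integer seed; the draw is deterministic given it.
#' @return object of class `tuning_model` with fields `baseline` (length
#'   n_channels), `gain` (n_channels x n_phonemes) and `group_informativeness`.
#' @export
build_tuning <- function(inventory, config,
                         informativeness = default_informativeness(),
                         seed = config$seed) {
  groups <- names(config$channel_groups)
  if (!setequal(names(informativeness), groups)) {
    stop_config("informativeness names must match channel groups (%s)",
                paste(groups, collapse = ", "))
  }
  P <- n_phonemes(inventory)
  with_seed(seed, {
    baseline <- stats::runif(config$n_channels, min = 5, max = 15)
    gain <- matrix(stats::rnorm(config$n_channels * P), config$n_channels, P)
    for (g in groups) {
      ch <- config$channel_groups[[g]]
      gain[ch, ] <- gain[ch, ] * informativeness[[g]]
    }
    gain[, sil_id(inventory)] <- 0
    structure(list(
      baseline = baseline,
      gain = gain,
      group_informativeness = informativeness[groups],
      inventory = inventory
    ), class = "tuning_model")
  })
}

#' Day-to-day drift model
#'
#' Parameters of the neural nonstationarity the recalibration machinery must
#' defeat: a per-channel multiplicative log-gain random walk, an additive
#' baseline random walk, and a small per-day probability that a channel goes
#' permanently silent.
#'
#' @param gain_drift_sd per-day sd of the per-channel log-gain increment.
#' @param offset_drift_sd per-day sd of the additive baseline increment.
#' @param dropout_prob per-day probability a channel drops out (gain set to
#'   zero from that day on).
#' @param seed default seed.
#' @return object of class `drift_model`.
#' @export
drift_model <- function(gain_drift_sd = 0.05, offset_drift_sd = 0.2,
                        dropout_prob = 0.005, seed = 1L) {
  stopifnot(gain_drift_sd >= 0, offset_drift_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(gain_drift_sd = gain_drift_sd,
                 offset_drift_sd = offset_drift_sd,
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed)), class = "drift_model")
}

#' Evolve a tuning model across days
#'
#' Day 1 is the input tuning unchanged; each later day applies one step of
#' the random walks and dropout of `drift`.
#'
#' @param tuning a [build_tuning()] result.
#' @param drift a [drift_model()].
#' @param n_days number of days (>= 1).
#' @param seed integer seed.
#' @return list of `tuning_model`, one per day.
#' @export
apply_drift <- function(tuning, drift, n_days, seed = drift$seed) {
  if (n_days < 1) stop_config("n_days must be >= 1")
  n_ch <- length(tuning$baseline)
  days <- vector("list", n_days)
  days[[1]] <- tuning
  if (n_days == 1) return(days)
  with_seed(seed, {
    cur <- tuning
    alive <- rep(TRUE, n_ch)
    for (d in 2:n_days) {
      mult <- exp(stats::rnorm(n_ch, 0, drift$gain_drift_sd))
      off <- stats::rnorm(n_ch, 0, drift$offset_drift_sd)
      drop_now <- stats::runif(n_ch) < drift$dropout_prob
      alive <- alive & !drop_now
      cur <- structure(list(
        baseline = pmax(cur$baseline + off, 0),
        gain = cur$gain * mult * as.numeric(alive),
        group_informativeness = cur$group_informativeness,
        inventory = cur$inventory
      ), class = "tuning_model")
      days[[d]] <- cur
    }
  })
  days
}

# Frame-label sequence for one sentence: leading/trailing/inter-word SIL plus
# per-phoneme durations (1 + geometric, mean = frames_per_phoneme_mean).
# Returns integer phoneme ids (1-based into inventory$symbols).
sentence_frame_labels <- function(words, lexicon, inventory, config) {
  prons <- lapply(words, function(w) lexicon_pron(lexicon, w))
  m <- config$frames_per_phoneme_mean
  sid <- sil_id(inventory)
  labs <- rep(sid, config$sil_frames)
  for (i in seq_along(prons)) {
    ph <- phoneme_id(inventory, prons[[i]])
    dur <- if (config$jitter_durations && m > 1) {
      1L + stats::rgeom(length(ph), prob = 1 / m)
    } else {
      rep(as.integer(round(m)), length(ph))
    }
    labs <- c(labs, rep(ph, times = dur))
    labs <- c(labs, rep(sid, config$sil_frames))
  }
  labs
}

#' Synthesize one attempted-speech trial
#'
#' Generates the frame labels and binned neural features for one attempted
#' sentence: silence at the boundaries and between words, each phoneme held
#' for a random integer number of 80 ms frames, and per-frame features
#' `baseline + amplitude * gain[, phoneme] + noise`, clipped at zero. The
#' amplitude factor scales the tuning modulation only (non-vocalized or
#' quiet attempts), never the baseline.
#'
#' @param words character vector of words (must all be in `lexicon`).
#' @param lexicon a [read_lexicon()] result.
#' @param tuning a [build_tuning()] (possibly drifted) model.
#' @param config a [session_config()].
#' @param amplitude attempt amplitude in (0, 1].
#' @param seed integer seed.
#' @return list with `features` (frames x channels) and `frame_labels`
#'   (integer ids into the inventory).
#' @export
synthesize_trial <- function(words, lexicon, tuning, config,
                             amplitude = 1, seed = config$seed) {
  stopifnot(amplitude > 0, amplitude <= 1)
  inventory <- tuning$inventory
  with_seed(seed, {
    labs <- sentence_frame_labels(words, lexicon, inventory, config)
    feats <- trial_features(labs, tuning, config, amplitude)
    list(features = feats, frame_labels = labs)
  })
}

trial_features <- function(labs, tuning, config, amplitude) {
  n_fr <- length(labs)
  n_ch <- length(tuning$baseline)
  mu <- matrix(tuning$baseline, n_fr, n_ch, byrow = TRUE) +
    amplitude * t(tuning$gain[, labs, drop = FALSE])
  noise <- if (config$noise_sd > 0) {
    matrix(stats::rnorm(n_fr * n_ch, 0, config$noise_sd), n_fr, n_ch)
  } else 0
  pmax(mu + noise, 0)
}

#' Synthesize a full session
#'
#' Concatenates trials for every sentence of `corpus` with inter-sentence
#' silence gaps and records per-sentence frame spans, the session day, and
#' per-sentence attempt amplitudes.
#'
#' @param corpus character vector of sentences (words separated by spaces) or
#'   list of word vectors.
#' @param lexicon lexicon holding all corpus words.
#' @param tuning tuning model for this day.
#' @param config a [session_config()].
#' @param day integer day index.
#' @param amplitude scalar or per-sentence vector of attempt amplitudes.
#' @param gap_frames extra silence frames between sentences.
#' @param seed integer seed.
#' @return object of class `neural_session`: `features`, `frame_labels`,
#'   `transcripts` (character), `spans` (data.frame sentence/start/end),
#'   `day`, `amplitude`, plus the inventory and config used.
#' @export
synthesize_session <- function(corpus, lexicon, tuning, config,
                               day = 1L, amplitude = 1,
                               gap_frames = config$sil_frames,
                               seed = config$seed) {
  if (length(corpus) == 0) stop_config("corpus must be nonempty")
  sentences <- corpus_words(corpus)
  amplitude <- rep_len(amplitude, length(sentences))
  inventory <- tuning$inventory
  sid <- sil_id(inventory)
  with_seed(seed, {
    feats_list <- vector("list", length(sentences))
    labs_list <- vector("list", length(sentences))
    spans <- data.frame(sentence = seq_along(sentences),
                        start = NA_integer_, end = NA_integer_)
    pos <- 0L
    for (i in seq_along(sentences)) {
      labs <- sentence_frame_labels(sentences[[i]], lexicon, inventory, config)
      if (i < length(sentences) && gap_frames > 0) {
        gap <- rep(sid, gap_frames)
        labs_full <- c(labs, gap)
      } else {
        labs_full <- labs
      }
      feats <- trial_features(labs_full, tuning, config, amplitude[i])
      spans$start[i] <- pos + 1L
      spans$end[i] <- pos + length(labs)
      pos <- pos + length(labs_full)
      feats_list[[i]] <- feats
      labs_list[[i]] <- labs_full
    }
    structure(list(
      features = do.call(rbind, feats_list),
      frame_labels = unlist(labs_list),
      transcripts = vapply(sentences, paste, "", collapse = " "),
      spans = spans,
      day = as.integer(day),
      amplitude = amplitude,
      inventory = inventory,
      config = config
    ), class = "neural_session")
  })
}

#' @export
print.neural_session <- function(x, ...) {
  cat(sprintf("<neural_session> day %d: %d frames x %d channels, %d sentences\n",
              x$day, nrow(x$features), ncol(x$features), nrow(x$spans)))
  invisible(x)
}

corpus_words <- function(corpus) {
  if (is.list(corpus)) lapply(corpus, as.character)
  else strsplit(tolower(as.character(corpus)), "\\s+")
}

#' Generate a sentence corpus from a vocabulary
#'
#' Samples sentences of random length with Zipf-weighted word frequencies, so
#' that some words are common and some rare in training data (which the
#' word-frequency evaluation exploits).
#'
#' @param vocabulary character vector of words.
#' @param n_sentences number of sentences.
#' @param words_min,words_max sentence length range (uniform).
#' @param zipf_s Zipf exponent; 0 gives uniform word frequencies.
#' @param seed integer seed.
#' @return character vector of sentences.
#' @export
make_corpus <- function(vocabulary, n_sentences, words_min = 3L,
                        words_max = 7L, zipf_s = 0.6, seed = 1L) {
  stopifnot(n_sentences >= 1, words_min >= 1, words_max >= words_min)
  w <- (seq_along(vocabulary))^(-zipf_s)
  with_seed(seed, {
    vapply(seq_len(n_sentences), function(i) {
      len <- sample(words_min:words_max, 1)
      paste(sample(vocabulary, len, replace = TRUE, prob = w), collapse = " ")
    }, "")
  })
}

#' Write / read a session as a plain-text container
#'
#' Persists a `neural_session` as a directory holding a JSON header
#' (day, bin width, channel groups, inventory, spans, transcripts,
#' amplitudes) plus TSV matrices for the features and frame labels.
#'
#' @param session a `neural_session`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    day = session$day, bin_ms = session$config$bin_ms,
    n_channels = ncol(session$features),
    channel_groups = session$config$channel_groups,
    inventory = session$inventory$symbols,
    transcripts = session$transcripts,
    amplitude = session$amplitude,
    spans = session$spans
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(session$features, file.path(path, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(as.character(session$frame_labels),
             file.path(path, "frame_labels.txt"))
  invisible(path)
}

#' @rdname write_session
#' @param config optional [session_config()] to attach on read (noise and
#'   timing fields are not stored in the container).
#' @export
read_session <- function(path, config = NULL) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  feats <- as.matrix(utils::read.table(file.path(path, "features.tsv"),
                                       sep = "\t"))
  dimnames(feats) <- NULL
  labs <- as.integer(readLines(file.path(path, "frame_labels.txt")))
  inv <- phoneme_inventory()
  if (!identical(inv$symbols, as.character(header$inventory))) {
    inv$symbols <- as.character(header$inventory)
    inv$index_of <- stats::setNames(seq_along(inv$symbols) - 1L, inv$symbols)
  }
  if (is.null(config)) {
    config <- session_config(n_channels = header$n_channels,
                             channel_groups = header$channel_groups)
  }
  structure(list(
    features = feats, frame_labels = labs,
    transcripts = header$transcripts,
    spans = as.data.frame(header$spans),
    day = as.integer(header$day),
    amplitude = as.numeric(header$amplitude),
    inventory = inv, config = config
  ), class = "neural_session")
}
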