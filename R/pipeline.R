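#' Decode every sentence of a session
#'
#' Runs the frame classifier and the beam search over each sentence span of
#' a session and pairs the decoded words with the reference transcript.
#'
#' @param model a `decoder_model`.
#' @param session a `neural_session`.
#' @param lexicon,lm decoding constraints.
#' @param beam a [beam_config()].
#' @param rescore_lm optional higher-order LM for n-best rescoring.
#' @param rescore_weight weight of the rescoring LM.
#' @return data.frame: `reference`, `hypothesis`, `frames`, `ref_phonemes`,
#'   `hyp_phonemes` (space-joined collapsed paths).
#' @export
decode_session <- function(model, session, lexicon, lm,
                           beam = beam_config(beam_width = 16L),
                           rescore_lm = NULL, rescore_weight = 1) {
  inv <- model$inventory
  n <- nrow(session$spans)
  out <- data.frame(reference = session$transcripts,
                    hypothesis = character(n), frames = integer(n),
                    ref_phonemes = character(n), hyp_phonemes = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fr <- seq(session$spans$start[i], session$spans$end[i])
    lp <- decode_frames(model, session$features[fr, , drop = FALSE])
    res <- beam_search(lp, lexicon, lm, beam, inv)
    if (!is.null(rescore_lm)) {
      res <- rescore_nbest(res, rescore_lm, rescore_weight, lexicon, lp, inv)
    }
    out$hypothesis[i] <- paste(res$words, collapse = " ")
    out$frames[i] <- length(fr)
    ref_words <- strsplit(tolower(session$transcripts[i]), "\\s+")[[1]]
    out$ref_phonemes[i] <- paste(
      unlist(lapply(ref_words, function(w) lexicon_pron(lexicon, w))),
      collapse = " ")
    out$hyp_phonemes[i] <- paste(
      collapse_path(inv$symbols[max.col(lp, ties.method = "first")]),
      collapse = " ")
  }
  out
}

#' Study configuration
#'
#' One container for the sub-configurations of an end-to-end simulated
#' study. All randomness derives from `master_seed`.
#'
#' @param experiment experiment name (used in the output manifest).
#' @param vocabulary_regime `"small"` (the packaged 50-word lexicon) or
#'   `"large"` (a synthetic vocabulary of `large_vocab_size` words).
#' @param large_vocab_size size of the large regime's vocabulary.
#' @param n_days simulated days; `sentences_per_day` training sentences each.
#' @param sentences_per_day training sentences per simulated day.
#' @param n_eval_sentences evaluation sentences per evaluated day.
#' @param words_min,words_max sentence length range of the corpora.
#' @param zipf_s Zipf exponent of the corpus word frequencies (0 = uniform).
#' @param lm_corpus_sentences size of the text corpus the language models
#'   are trained on.
#' @param session,drift,training,recalibration,beam,conversation sub-configs.
#' @param n_seeds replicate seeds for multi-seed studies.
#' @param output_dir optional directory for report files (`NULL`: no files).
#' @param master_seed master integer seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(experiment = "copy_task",
                         vocabulary_regime = c("small", "large"),
                         large_vocab_size = 5000L,
                         n_days = 1L,
                         sentences_per_day = 290L,
                         n_eval_sentences = 40L,
                         words_min = 3L, words_max = 7L,
                         zipf_s = 0.6,
                         lm_corpus_sentences = 600L,
                         session = session_config(),
                         drift = drift_model(),
                         training = training_config(),
                         recalibration = recalibration_config(),
                         beam = beam_config(beam_width = 16L),
                         conversation = conversation_config(),
                         n_seeds = 1L,
                         output_dir = NULL,
                         master_seed = 1L) {
  vocabulary_regime <- match.arg(vocabulary_regime)
  stopifnot(n_days >= 1, sentences_per_day >= 1, n_eval_sentences >= 1)
  structure(list(
    experiment = experiment, vocabulary_regime = vocabulary_regime,
    large_vocab_size = as.integer(large_vocab_size),
    n_days = as.integer(n_days),
    sentences_per_day = as.integer(sentences_per_day),
    n_eval_sentences = as.integer(n_eval_sentences),
    words_min = as.integer(words_min), words_max = as.integer(words_max),
    zipf_s = zipf_s,
    lm_corpus_sentences = as.integer(lm_corpus_sentences),
    session = session, drift = drift, training = training,
    recalibration = recalibration, beam = beam,
    conversation = conversation, n_seeds = as.integer(n_seeds),
    output_dir = output_dir, master_seed = as.integer(master_seed)
  ), class = "study_config")
}

study_lexicon <- function(config, seed) {
  if (config$vocabulary_regime == "small") lexicon_50()
  else synthetic_lexicon(config$large_vocab_size, seed = seed)
}

# Train the in-beam bigram and rescoring trigram on a shared text corpus.
study_lms <- function(vocab, config, seed) {
  corpus <- make_corpus(vocab, config$lm_corpus_sentences,
                        config$words_min, config$words_max,
                        zipf_s = config$zipf_s, seed = seed)
  list(lm = train_ngram(corpus, order = 2L, vocabulary = vocab),
       rescore = train_ngram(corpus, order = 3L, vocabulary = vocab),
       corpus = corpus)
}

write_study_outputs <- function(config, name, report_obj) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(experiment = config$experiment, study = name,
                   master_seed = config$master_seed,
                   package_version = as.character(utils::packageVersion("neurotext")),
                   vocabulary_regime = config$vocabulary_regime,
                   n_days = config$n_days,
                   sentences_per_day = config$sentences_per_day)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir,
                                 paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report_obj,
                       file.path(config$output_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Copy-task study
#'
#' The prompted-sentence paradigm: simulate training sessions, train the
#' frame decoder, decode held-out evaluation sentences with the
#' lexicon-constrained beam search plus trigram rescoring, and report
#' session-level error rates with bootstrap confidence intervals.
#'
#' @param config a [study_config()].
#' @return list: `report` (a [session_report()]), `results` (per-sentence
#'   decode table), `training_corpus`, `word_frequency` (the per-word error
#'   vs training-count analysis).
#' @export
run_copy_task_study <- function(config = study_config()) {
  seeds <- derive_seeds(config$master_seed, 8)
  lexicon <- study_lexicon(config, seeds[1])
  vocab <- vocabulary(lexicon)
  lms <- study_lms(vocab, config, seeds[2])
  tuning <- build_tuning(phoneme_inventory(), config$session,
                         seed = seeds[3])
  train_corpus <- make_corpus(vocab, config$sentences_per_day * config$n_days,
                              config$words_min, config$words_max,
                              zipf_s = config$zipf_s, seed = seeds[4])
  eval_corpus <- make_corpus(vocab, config$n_eval_sentences,
                             config$words_min, config$words_max,
                             zipf_s = config$zipf_s, seed = seeds[5])
  train_sessions <- lapply(seq_len(config$n_days), function(d) {
    idx <- seq_len(config$sentences_per_day) +
      (d - 1L) * config$sentences_per_day
    synthesize_session(train_corpus[idx], lexicon, tuning, config$session,
                       day = d, seed = as.numeric(seeds[6]) + d)
  })
  eval_session <- synthesize_session(eval_corpus, lexicon, tuning,
                                     config$session,
                                     day = config$n_days,
                                     seed = seeds[7])
  model <- train_decoder(train_sessions, config = config$training)
  results <- decode_session(model, eval_session, lexicon, lms$lm,
                            config$beam, rescore_lm = lms$rescore)
  report <- session_report(results, n_resamples = 2000L, seed = seeds[8])
  wf <- word_error_vs_training_count(results, train_corpus)
  out <- list(report = report, results = results,
              training_corpus = train_corpus, word_frequency = wf,
              model = model, lexicon = lexicon, lms = lms)
  write_study_outputs(config, "copy_task",
                      list(report = unclass(report), results = results))
  out
}

#' Multi-day stability study
#'
#' Simulates drifting days and compares three calibration strategies:
#' a decoder frozen after day 1, a decoder seeded on the first days then
#' frozen ("pooled"), and a decoder recalibrated every day on 20
#' ground-truth sentences. Reports per-day word error rates for each
#' strategy across replicate seeds.
#'
#' @param config a [study_config()] with `n_days >= 2`.
#' @param n_pool_days days pooled by the seeded strategy.
#' @return list: `wer` (data.frame seed/day/strategy/wer), `config` echoes.
#' @export
run_stability_study <- function(config = study_config(
                                  n_days = 21L, sentences_per_day = 60L,
                                  n_eval_sentences = 5L, n_seeds = 10L,
                                  zipf_s = 0),
                                n_pool_days = 5L,
                                eval_days = NULL) {
  if (config$n_days < 2) stop_config("stability study needs >= 2 days")
  eval_days <- sort(unique(as.integer(eval_days %||% seq_len(config$n_days))))
  stopifnot(all(eval_days >= 1), all(eval_days <= config$n_days))
  lexicon <- study_lexicon(config, derive_seeds(config$master_seed, 1))
  vocab <- vocabulary(lexicon)
  lms <- study_lms(vocab, config, derive_seeds(config$master_seed + 1, 1))
  n_calib <- config$recalibration$n_calib_sentences
  rows <- list()
  for (s in seq_len(config$n_seeds)) {
    seeds <- derive_seeds(config$master_seed + 100 * s, 6 + 2 * config$n_days)
    tuning0 <- build_tuning(phoneme_inventory(), config$session,
                            seed = seeds[1])
    tunings <- apply_drift(tuning0, config$drift, config$n_days,
                           seed = seeds[2])
    # day 1: full training session; later days: calibration-sized sessions
    # (the 20 prompted sentences the recalibrated strategy sees).
    # pooled seeds on the first n_pool_days full sessions.
    pool_days <- seq_len(min(n_pool_days, config$n_days))
    day_sessions <- lapply(seq_len(config$n_days), function(d) {
      n_sent <- if (d %in% pool_days) config$sentences_per_day else n_calib
      corpus <- make_corpus(vocab, n_sent, config$words_min,
                            config$words_max, zipf_s = config$zipf_s,
                            seed = seeds[4 + 2 * d])
      synthesize_session(corpus, lexicon, tunings[[d]], config$session,
                         day = d, seed = seeds[5 + 2 * d])
    })
    eval_sessions <- lapply(eval_days, function(d) {
      corpus <- make_corpus(vocab, config$n_eval_sentences,
                            config$words_min, config$words_max,
                            zipf_s = config$zipf_s,
                            seed = as.numeric(seeds[3]) + d)
      synthesize_session(corpus, lexicon, tunings[[d]], config$session,
                         day = d, seed = as.numeric(seeds[4]) + d)
    })
    names(eval_sessions) <- eval_days
    frozen <- train_decoder(day_sessions[[1]], config = config$training)
    pooled <- train_decoder(day_sessions[pool_days],
                            config = config$training)
    recal <- frozen
    for (d in seq_len(config$n_days)) {
      if (d > 1) {
        recal <- fine_tune(recal, day_sessions[[d]], config$recalibration)
      }
      if (!(d %in% eval_days)) next
      ev <- eval_sessions[[as.character(d)]]
      for (strat in c("frozen", "pooled", "recalibrated")) {
        model <- switch(strat, frozen = frozen, pooled = pooled,
                        recalibrated = recal)
        res <- decode_session(model, ev, lexicon, lms$lm, config$beam)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, day = d, strategy = strat,
          wer = wer(res$reference, res$hypothesis),
          frame_accuracy = frame_accuracy(model, ev),
          stringsAsFactors = FALSE)
      }
    }
  }
  wer_tab <- do.call(rbind, rows)
  write_study_outputs(config, "stability", list(wer = wer_tab))
  list(wer = wer_tab, n_days = config$n_days, n_seeds = config$n_seeds,
       eval_days = eval_days)
}

#' Conversation-mode study
#'
#' Simulates self-paced speech streams with long pauses, detects sentence
#' events from neural activity alone, decodes each detected segment, and
#' aggregates self-reports and the false-detection rate on a speech-free
#' stream.
#'
#' @param config a [study_config()].
#' @param n_conversation_sentences sentences in the simulated stream.
#' @param no_report_prob probability a sentence gets no self-report.
#' @param silence_minutes duration of the speech-free stream for the
#'   false-detection measurement.
#' @param seg_pad frames of context added on both sides of a detected
#'   segment before decoding (compensates the causal smoothing lag of the
#'   onset detector).
#' @return list: `events` (decoded sentence events with self-reports),
#'   `report` (a [session_report()] with the conversation block), `wer_detected`,
#'   `wer_oracle`, `false_detections_per_hour`.
#' @export
run_conversation_study <- function(config = study_config(),
                                   n_conversation_sentences = 20L,
                                   no_report_prob = 0.05,
                                   silence_minutes = 60,
                                   seg_pad = 8L) {
  seeds <- derive_seeds(config$master_seed + 7, 10)
  lexicon <- study_lexicon(config, seeds[1])
  vocab <- vocabulary(lexicon)
  lms <- study_lms(vocab, config, seeds[2])
  tuning <- build_tuning(phoneme_inventory(), config$session, seed = seeds[3])
  train_corpus <- make_corpus(vocab, config$sentences_per_day,
                              config$words_min, config$words_max,
                              seed = seeds[4])
  train_session <- synthesize_session(train_corpus, lexicon, tuning,
                                      config$session, seed = seeds[5])
  model <- train_decoder(train_session, config = config$training)
  detector <- train_detector(train_session, seed = seeds[6])
  conv_corpus <- make_corpus(vocab, n_conversation_sentences,
                             config$words_min, config$words_max,
                             seed = seeds[7])
  stream <- synthesize_conversation(conv_corpus, lexicon, tuning,
                                    config$session, seed = seeds[8])
  segs <- detect_segments(detector, stream$features, config$conversation)
  # pair each detected segment with the overlapping true sentence
  events <- list()
  with_seed(seeds[9], {
    for (i in seq_len(nrow(segs))) {
      a <- max(1L, segs$start[i] - seg_pad)
      b <- min(nrow(stream$features), segs$end[i] + seg_pad)
      lp <- decode_frames(model, stream$features[a:b, , drop = FALSE])
      res <- beam_search(lp, lexicon, lms$lm, config$beam, model$inventory)
      hyp <- paste(res$words, collapse = " ")
      ov <- which(stream$truth$start <= segs$end[i] &
                    stream$truth$end >= segs$start[i])
      ref <- if (length(ov)) paste(stream$truth$text[ov], collapse = " ")
             else ""
      self_report <- if (stats::runif(1) < no_report_prob) "none"
                     else if (identical(hyp, ref)) "correct" else "incorrect"
      events[[i]] <- data.frame(start = segs$start[i], end = segs$end[i],
                                cause = segs$cause[i], reference = ref,
                                hypothesis = hyp, self_report = self_report,
                                stringsAsFactors = FALSE)
    }
  })
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(start = integer(0), end = integer(0), cause = character(0),
               reference = character(0), hypothesis = character(0),
               self_report = character(0))
  wer_detected <- if (nrow(events) > 0 && any(events$reference != "")) {
    keep <- events$reference != ""
    wer(events$reference[keep], events$hypothesis[keep])
  } else NA_real_
  # oracle segmentation: decode the true spans directly
  oracle <- vapply(seq_len(nrow(stream$truth)), function(i) {
    lp <- decode_frames(model,
                        stream$features[stream$truth$start[i]:stream$truth$end[i], ,
                                        drop = FALSE])
    paste(beam_search(lp, lexicon, lms$lm, config$beam,
                      model$inventory)$words, collapse = " ")
  }, "")
  wer_oracle <- wer(stream$truth$text, oracle)
  # false detections on a pure-silence stream
  sil_frames <- as.integer(round(silence_minutes * 60 * 1000 /
                                   config$session$bin_ms))
  sil_stream <- with_seed(seeds[10],
    trial_features(rep(sil_id(model$inventory), sil_frames), tuning,
                   config$session, amplitude = 1))
  fdr <- false_detection_rate(detector, sil_stream, config$conversation)
  report <- session_report(conversation_log = events)
  out <- list(events = events, report = report,
              wer_detected = wer_detected, wer_oracle = wer_oracle,
              false_detections_per_hour = fdr)
  write_study_outputs(config, "conversation",
                      list(events = events, wer_detected = wer_detected,
                           wer_oracle = wer_oracle,
                           false_detections_per_hour = fdr))
  out
}

#' Write decode results as JSON lines
#'
#' @param results data.frame from [decode_session()].
#' @param path output file.
#' @export
write_results_jsonl <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    writeLines(jsonlite::toJSON(as.list(results[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
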