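#' Conversation-mode configuration
#'
#' Self-paced use: a sentence is finalized after a fixed period of speech
#' inactivity. At the 80 ms frame rate the default 6 s timeout is exactly 75
#' frames.
#'
#' @param inactivity_timeout_s seconds of continuous sub-threshold activity
#'   that finalize a sentence (default 6).
#' @param bin_ms frame duration (80).
#' @param min_sentence_frames segments shorter than this are discarded.
#' @return object of class `conversation_config` with the derived
#'   `timeout_frames`.
#' @export
conversation_config <- function(inactivity_timeout_s = 6, bin_ms = 80L,
                                min_sentence_frames = 3L) {
  if (bin_ms != 80L) stop_config("bin_ms is fixed at 80 ms")
  structure(list(inactivity_timeout_s = inactivity_timeout_s,
                 bin_ms = 80L,
                 timeout_frames = as.integer(round(1000 * inactivity_timeout_s /
                                                     bin_ms)),
                 min_sentence_frames = as.integer(min_sentence_frames)),
            class = "conversation_config")
}

#' Train a neural speech-activity detector
#'
#' Energy-based frame detector for the onset/offset state machine. Attempted
#' speech modulates tuned channels in both directions around baseline, so
#' the discriminating statistic is deviation energy, not the raw rate: per
#' frame, the detector averages the squared normalized deviation over
#' channels with non-negative weights learned from the speech/silence
#' contrast (a matched filter on channel informativeness), smooths the
#' statistic with a short causal moving average, and converts it to a speech
#' probability through a logistic link on its z-score relative to silence.
#' The weights and the silence statistics are estimated on disjoint frame
#' halves (cross-fitting), so that weight selection cannot bias the silence
#' baseline the thresholds are anchored to.
#'
#' @param sessions list of `neural_session` with frame labels (SIL = silence).
#' @param smooth_window frames in the causal moving average of the energy
#'   statistic (default 5, i.e. 400 ms).
#' @param theta_on onset threshold on the calibrated probability (0.8 at the
#'   defaults corresponds to about 5.4 silence standard deviations).
#' @param theta_off offset threshold (`0 < theta_off <= theta_on < 1`).
#' @param z_center silence z-score mapped to probability 0.5.
#' @param seed integer seed (recorded; the fit itself is closed-form /
#'   deterministic).
#' @return object of class `speech_detector`: `normalizer`, `weights`
#'   (per-channel), `calibration` (intercept, slope of the logistic link),
#'   thresholds, window.
#' @export
train_detector <- function(sessions, smooth_window = 5L, theta_on = 0.8,
                           theta_off = 0.4, z_center = 4, seed = 1L) {
  if (!(theta_off > 0 && theta_off <= theta_on && theta_on < 1)) {
    stop_config("need 0 < theta_off <= theta_on < 1")
  }
  if (inherits(sessions, "neural_session")) sessions <- list(sessions)
  sid <- sil_id(sessions[[1]]$inventory)
  X <- do.call(rbind, lapply(sessions, function(s) s$features))
  y <- unlist(lapply(sessions, function(s) s$frame_labels != sid))
  if (length(unique(y)) < 2) {
    stop_config("need both speech and silence frames to train the detector")
  }
  stats <- fit_normalizer(X)
  Z2 <- normalize_features(X, stats)^2
  # cross-fit: contrast weights from even frames, silence calibration from
  # odd frames
  even <- seq_len(nrow(Z2)) %% 2 == 0
  v <- pmax(colMeans(Z2[y & even, , drop = FALSE]) -
              colMeans(Z2[!y & even, , drop = FALSE]), 0)
  if (sum(v) == 0) v[] <- 1  # no contrast: fall back to uniform energy
  v <- v / sum(v)
  T1 <- as.numeric(Z2 %*% v)
  mu_sil <- mean(T1[!y & !even])
  sd_sil <- stats::sd(T1[!y & !even])
  if (!is.finite(sd_sil) || sd_sil < 1e-12) sd_sil <- 1e-12
  sd_smooth <- sd_sil / sqrt(smooth_window)
  calib <- c(-mu_sil / sd_smooth - z_center, 1 / sd_smooth)
  structure(list(normalizer = stats, weights = v,
                 calibration = calib,
                 smooth_window = as.integer(smooth_window),
                 theta_on = theta_on, theta_off = theta_off,
                 seed = as.integer(seed)),
            class = "speech_detector")
}

# causal moving average with a window shortened at the stream start
causal_mean <- function(x, w) {
  if (w <= 1L) return(as.numeric(x))
  cs <- cumsum(x)
  idx <- seq_along(x)
  lo <- pmax(idx - w + 1L, 1L)
  (cs - c(0, cs)[lo]) / (idx - lo + 1L)
}

# Calibrated, smoothed per-frame speech probability.
speech_probability <- function(detector, features) {
  Tt <- normalize_features(features, detector$normalizer)^2 %*%
    detector$weights
  Ts <- causal_mean(Tt, detector$smooth_window)
  stats::plogis(detector$calibration[1] + detector$calibration[2] * Ts)
}

#' Segment a feature stream into sentence events
#'
#' Hysteresis state machine on the smoothed speech probability: an onset
#' opens a segment when the probability reaches `theta_on`; the segment's
#' end is the last frame at or above `theta_off`; the sentence is finalized
#' once the probability has stayed below `theta_off` for the inactivity
#' timeout (75 consecutive frames at the defaults: 6 s of 80 ms bins). A
#' still-open segment at the end of the stream is finalized there with cause
#' `"manual"` (the optional end-now button).
#'
#' @param detector a [train_detector()] result.
#' @param features frames x channels stream.
#' @param config a [conversation_config()].
#' @return data.frame of sentence events: `start`, `end`, `finalized_at`,
#'   `cause` (`"timeout"` or `"manual"`).
#' @export
detect_segments <- function(detector, features, config = conversation_config()) {
  p <- speech_probability(detector, features)
  out <- run_hysteresis(p, detector$theta_on, detector$theta_off,
                        config$timeout_frames)
  out[out$end - out$start + 1L >= config$min_sentence_frames, , drop = FALSE]
}

# The hysteresis state machine on a per-frame speech probability: onset at
# p >= theta_on; the segment end is the last frame with p >= theta_off; a
# sentence is finalized once p has stayed below theta_off for
# `timeout_frames` consecutive frames. A segment still open at stream end is
# finalized there with cause "manual".
run_hysteresis <- function(p, theta_on, theta_off, timeout_frames) {
  n <- length(p)
  events <- list()
  state <- "idle"
  start <- NA_integer_; last_active <- NA_integer_
  for (t in seq_len(n)) {
    if (state == "idle") {
      if (p[t] >= theta_on) {
        state <- "active"
        start <- t
        last_active <- t
      }
    } else {
      if (p[t] >= theta_off) {
        last_active <- t
      } else if (t - last_active >= timeout_frames) {
        events[[length(events) + 1L]] <-
          list(start = start, end = last_active, finalized_at = t,
               cause = "timeout")
        state <- "idle"
      }
    }
  }
  if (state == "active") {
    events[[length(events) + 1L]] <-
      list(start = start, end = last_active, finalized_at = n,
           cause = "manual")
  }
  if (length(events) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      finalized_at = integer(0), cause = character(0)))
  }
  data.frame(
    start = vapply(events, `[[`, 0L, "start"),
    end = vapply(events, `[[`, 0L, "end"),
    finalized_at = vapply(events, `[[`, 0L, "finalized_at"),
    cause = vapply(events, `[[`, "", "cause"),
    stringsAsFactors = FALSE
  )
}

#' False-detection rate on a speech-free stream
#'
#' Number of onset events per hour of a stream known to contain no speech.
#'
#' @inheritParams detect_segments
#' @return detections per hour (scalar).
#' @export
false_detection_rate <- function(detector, features,
                                 config = conversation_config()) {
  if (is.null(nrow(features)) || nrow(features) == 0) {
    stop_config("zero-length stream")
  }
  p <- speech_probability(detector, features)
  onsets <- nrow(run_hysteresis(p, detector$theta_on, detector$theta_off,
                                config$timeout_frames))
  hours <- nrow(features) * config$bin_ms / 3.6e6
  onsets / hours
}

#' Simulate a self-paced conversation stream
#'
#' Concatenates attempted sentences separated by long silences (longer than
#' the finalization timeout) into one continuous feature stream, the input
#' for conversation-mode detection and decoding.
#'
#' @param corpus character vector of sentences.
#' @param lexicon,tuning,config as for [synthesize_session()].
#' @param pause_frames_range range of the inter-sentence silence gaps.
#' @param lead_frames silence before the first sentence.
#' @param seed integer seed.
#' @return list: `features`, `frame_labels`, `truth` (data.frame with per
#'   sentence `text`, `start`, `end`).
#' @export
synthesize_conversation <- function(corpus, lexicon, tuning, config,
                                    pause_frames_range = c(85L, 140L),
                                    lead_frames = 20L, seed = config$seed) {
  sentences <- corpus_words(corpus)
  inventory <- tuning$inventory
  sid <- sil_id(inventory)
  with_seed(seed, {
    labs <- rep(sid, lead_frames)
    truth <- data.frame(text = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    for (i in seq_along(sentences)) {
      sl <- sentence_frame_labels(sentences[[i]], lexicon, inventory, config)
      # truth span covers speech content only, not boundary silence
      speech <- which(sl != sid)
      truth <- rbind(truth, data.frame(
        text = paste(sentences[[i]], collapse = " "),
        start = length(labs) + min(speech),
        end = length(labs) + max(speech), stringsAsFactors = FALSE))
      labs <- c(labs, sl)
      pause <- sample(pause_frames_range[1]:pause_frames_range[2], 1)
      labs <- c(labs, rep(sid, pause))
    }
    feats <- trial_features(labs, tuning, config, amplitude = 1)
    list(features = feats, frame_labels = labs, truth = truth)
  })
}
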