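test_that("normalizer centers and scales, floors constant channels", {
  set.seed(2)
  X <- matrix(rnorm(500, mean = 3, sd = 2), 100, 5)
  st <- fit_normalizer(X)
  Z <- normalize_features(X, st)
  expect_equal(colMeans(Z), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(Z, 2, sd), rep(1, 5), tolerance = 1e-6)

  X[, 3] <- 7
  expect_warning(st2 <- fit_normalizer(X), "floored")
  expect_true(all(is.finite(normalize_features(X, st2))))
  expect_error(fit_normalizer(X[1, , drop = FALSE]), "2 frames")
})

test_that("day-1 statistics applied to a drifted day reveal the drift", {
  cfg <- small_config()
  lex <- tiny_lexicon()
  tun <- build_tuning(test_inv, cfg, seed = 3)
  days <- apply_drift(tun, drift_model(offset_drift_sd = 0.5), 15, seed = 4)
  corpus <- make_corpus(vocabulary(lex), 10, seed = 5)
  s1 <- synthesize_session(corpus, lex, days[[1]], cfg, seed = 6)
  s15 <- synthesize_session(corpus, lex, days[[15]], cfg, seed = 7)
  st <- fit_normalizer(s1$features)
  drifted_means <- colMeans(normalize_features(s15$features, st))
  expect_gt(mean(abs(drifted_means)), 0.2)
})

test_that("context stacking replicates edges", {
  X <- matrix(1:10, 5, 2)
  S <- neurotext:::stack_context(X, 1, 1)
  expect_equal(ncol(S), 6)
  expect_equal(S[1, 1:2], X[1, ])   # left edge replicated
  expect_equal(S[5, 5:6], X[5, ])   # right edge replicated
  expect_equal(S[3, 3:4], X[3, ])   # center block is the frame itself
  expect_equal(S[3, 1:2], X[2, ])
  expect_equal(S[3, 5:6], X[4, ])
})

test_that("training is deterministic and recovers noiseless labels", {
  cfg <- small_config(noise_sd = 0)
  lex <- tiny_lexicon()
  tun <- build_tuning(test_inv, cfg, seed = 8)
  tr <- synthesize_session(make_corpus(vocabulary(lex), 25, seed = 1),
                           lex, tun, cfg, seed = 2)
  ev <- synthesize_session(make_corpus(vocabulary(lex), 8, seed = 3),
                           lex, tun, cfg, seed = 4)
  m1 <- train_decoder(tr, config = training_config(epochs = 20, seed = 9))
  m2 <- train_decoder(tr, config = training_config(epochs = 20, seed = 9))
  expect_identical(m1$W, m2$W)
  expect_gte(frame_accuracy(m1, ev), 0.99)
  expect_equal(length(m1$loss_history), 20L)
  expect_true(all(diff(m1$loss_history) <= 1e-12))
})

test_that("decoder output rows are normalized log-probabilities", {
  fx <- copy_fixture()
  lp <- decode_frames(fx$model, fx$eval_session$features[1:40, ])
  expect_equal(apply(lp, 1, function(r) log(sum(exp(r)))), rep(0, 40),
               tolerance = 1e-9)
  one <- decode_frames(fx$model, fx$eval_session$features[1, , drop = FALSE])
  expect_equal(dim(one), c(1L, 40L))
  expect_error(decode_frames(fx$model, matrix(0, 5, 7)), "mismatch")
})

test_that("degenerate configurations are rejected", {
  expect_error(training_config(epochs = 0), "epochs")
  cfg <- small_config()
  lex <- tiny_lexicon()
  tun <- build_tuning(test_inv, cfg, seed = 1)
  ses <- synthesize_session("hi", lex, tun, cfg, seed = 2)
  ses$frame_labels[] <- sil_id(test_inv)
  expect_error(train_decoder(ses), "single-class")
  expect_error(recalibration_config(n_calib_sentences = 0), "n_calib")
})

test_that("fine-tuning: identity at zero epochs, no harm same-day, gain on drifted day", {
  fx <- copy_fixture()
  same <- fine_tune(fx$model, fx$train_session,
                    recalibration_config(epochs = 0))
  expect_identical(same, fx$model)

  acc_before <- frame_accuracy(fx$model, fx$eval_session)
  tuned_same_day <- fine_tune(fx$model, fx$train_session,
                              recalibration_config(epochs = 10))
  expect_gte(frame_accuracy(tuned_same_day, fx$eval_session),
             acc_before - 0.01)
  # the input model is unchanged by fine-tuning
  expect_equal(frame_accuracy(fx$model, fx$eval_session), acc_before)

  days <- apply_drift(fx$tuning, drift_model(), 15, seed = 21)
  corpus <- make_corpus(fx$vocab, 20, seed = 22)
  drifted <- synthesize_session(corpus, fx$lexicon, days[[15]], fx$config,
                                day = 15L, seed = 23)
  ev_drift <- synthesize_session(make_corpus(fx$vocab, 10, seed = 24),
                                 fx$lexicon, days[[15]], fx$config,
                                 day = 15L, seed = 25)
  frozen_acc <- frame_accuracy(fx$model, ev_drift)
  tuned <- fine_tune(fx$model, drifted, recalibration_config())
  expect_gt(frame_accuracy(tuned, ev_drift), frozen_acc)
})

test_that("pseudo-label recalibration needs a decode handle and then works", {
  fx <- copy_fixture()
  expect_error(fine_tune(fx$model, fx$train_session,
                         recalibration_config(mode = "pseudo_label")),
               "decode_handle")
  handle <- list(lexicon = fx$lexicon, lm = fx$lm,
                 beam_config = beam_config(beam_width = 8L))
  tuned <- fine_tune(fx$model, fx$eval_session,
                     recalibration_config(mode = "pseudo_label",
                                          n_calib_sentences = 5L,
                                          epochs = 5L),
                     decode_handle = handle)
  expect_s3_class(tuned, "decoder_model")
  expect_gte(frame_accuracy(tuned, fx$eval_session), 0.8)
})

test_that("pooling several days beats a single-day decoder under drift", {
  cfg <- small_config()
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  wins <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    tun <- build_tuning(test_inv, cfg, seed = 30 + s)
    days <- apply_drift(tun, drift_model(), 6, seed = 60 + s)
    sessions <- lapply(1:5, function(d)
      synthesize_session(make_corpus(vocab, 8, seed = 100 * s + d), lex,
                         days[[d]], cfg, day = d, seed = 200 * s + d))
    ev6 <- synthesize_session(make_corpus(vocab, 8, seed = 300 + s), lex,
                              days[[6]], cfg, day = 6L, seed = 400 + s)
    tc <- training_config(epochs = 15)
    single <- train_decoder(sessions[[1]], config = tc)
    pooled <- train_decoder(sessions, config = tc)
    if (frame_accuracy(pooled, ev6) > frame_accuracy(single, ev6)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, ceiling(0.8 * n_seeds))
})

test_that("decoder serialization round-trips", {
  fx <- copy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_decoder(fx$model, path)
  back <- load_decoder(path)
  expect_equal(back$W, fx$model$W, tolerance = 1e-12)
  expect_equal(back$normalizer$mean, fx$model$normalizer$mean,
               tolerance = 1e-12)
  lp1 <- decode_frames(fx$model, fx$eval_session$features[1:10, ])
  lp2 <- decode_frames(back, fx$eval_session$features[1:10, ])
  expect_equal(lp1, lp2, tolerance = 1e-9)
})
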