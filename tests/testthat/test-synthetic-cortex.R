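test_that("phoneme inventory is well-formed", {
  expect_length(test_inv$symbols, 40L)
  expect_true("SIL" %in% test_inv$symbols)
  expect_false(anyDuplicated(test_inv$symbols) > 0)
  expect_identical(unname(test_inv$index_of), seq_along(test_inv$symbols) - 1L)
})

test_that("tuning construction: zero case, determinism, informativeness ordering", {
  cfg <- small_config()
  zero <- build_tuning(test_inv, cfg,
                       informativeness = c(v6v = 0, `55b` = 0, `4` = 0,
                                           d6v = 0), seed = 3)
  expect_true(all(zero$gain == 0))
  expect_true(all(zero$baseline > 0))

  t1 <- build_tuning(test_inv, cfg, seed = 5)
  t2 <- build_tuning(test_inv, cfg, seed = 5)
  expect_identical(t1, t2)

  inf <- default_informativeness()
  tun <- build_tuning(test_inv, cfg, informativeness = inf, seed = 7)
  speech <- setdiff(seq_along(test_inv$symbols), sil_id(test_inv))
  gm <- vapply(names(cfg$channel_groups), function(g)
    mean(abs(tun$gain[cfg$channel_groups[[g]], speech])), 0)
  expect_true(gm[["v6v"]] > gm[["55b"]])
  expect_true(gm[["55b"]] > gm[["4"]])
  expect_true(gm[["4"]] > gm[["d6v"]])

  expect_error(build_tuning(test_inv, cfg,
                            informativeness = c(bogus = 1, `55b` = 1,
                                                `4` = 1, d6v = 1)),
               "match channel groups")
})

test_that("drift: identity at zero scales, forced dropout, random-walk growth", {
  cfg <- small_config()
  tun <- build_tuning(test_inv, cfg, seed = 1)
  still <- apply_drift(tun, drift_model(0, 0, 0), 5, seed = 2)
  for (d in 2:5) expect_equal(still[[d]]$gain, tun$gain)

  dead <- apply_drift(tun, drift_model(0, 0, 1), 3, seed = 2)
  expect_true(all(dead[[2]]$gain == 0))
  expect_true(all(dead[[3]]$gain == 0))

  expect_error(apply_drift(tun, drift_model(), 0), "n_days")

  # mean |log gain ratio| grows as sqrt(day - 1): Monte-Carlo over 200 seeds
  dm <- drift_model(gain_drift_sd = 0.1, offset_drift_sd = 0,
                    dropout_prob = 0)
  disp <- vapply(1:200, function(s) {
    days <- apply_drift(tun, dm, 5, seed = 1000 + s)
    ratio_d2 <- log(days[[2]]$gain[, 1] / tun$gain[, 1])
    ratio_d5 <- log(days[[5]]$gain[, 1] / tun$gain[, 1])
    c(mean(abs(ratio_d2)), mean(abs(ratio_d5)))
  }, c(0, 0))
  growth <- mean(disp[2, ]) / mean(disp[1, ])
  expect_equal(growth, sqrt(4), tolerance = 0.05)
})

test_that("drift gain-ratio distribution matches the stated random walk (KS)", {
  cfg <- session_config(n_channels = 1000L,
                        channel_groups = list(all = 1:1000))
  tun <- build_tuning(test_inv, cfg,
                      informativeness = c(all = 1), seed = 9)
  sdd <- 0.1
  days <- apply_drift(tun, drift_model(sdd, 0, 0), 8, seed = 10)
  lr <- log(days[[8]]$gain[, 2] / tun$gain[, 2])
  ks <- suppressWarnings(stats::ks.test(lr, "pnorm", 0, sdd * sqrt(7)))
  expect_gt(ks$p.value, 0.01)
})

test_that("trial synthesis: label arithmetic, noiseless identity, amplitude scaling", {
  cfg <- small_config(noise_sd = 0, frames_per_phoneme_mean = 2,
                      sil_frames = 2L, jitter_durations = FALSE)
  tun <- build_tuning(test_inv, cfg, seed = 4)
  lex <- tiny_lexicon()
  tr <- synthesize_trial("hi", lex, tun, cfg, seed = 6)
  expect_identical(test_inv$symbols[tr$frame_labels],
                   c("SIL", "SIL", "HH", "HH", "AY", "AY", "SIL", "SIL"))

  # noiseless identity: feature row = baseline + gain column of the label
  for (t in seq_along(tr$frame_labels)) {
    expect_equal(tr$features[t, ],
                 pmax(tun$baseline + tun$gain[, tr$frame_labels[t]], 0))
  }

  # amplitude multiplies the deviation from baseline exactly (noise-free)
  full <- synthesize_trial("cat", lex, tun, cfg, amplitude = 1, seed = 8)
  half <- synthesize_trial("cat", lex, tun, cfg, amplitude = 0.5, seed = 8)
  dev_full <- sweep(full$features, 2, tun$baseline)
  dev_half <- sweep(half$features, 2, tun$baseline)
  expect_equal(dev_half, dev_full / 2)

  expect_error(synthesize_trial("zebra", lex, tun, cfg), "zebra")
})

test_that("session synthesis: structure, determinism, label recovery, SIL fraction", {
  cfg <- small_config()
  tun <- build_tuning(test_inv, cfg, seed = 4)
  lex <- tiny_lexicon()
  corpus <- make_corpus(vocabulary(lex), 20, seed = 1)
  s1 <- synthesize_session(corpus, lex, tun, cfg, seed = 2)
  s2 <- synthesize_session(corpus, lex, tun, cfg, seed = 2)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$spans), 20L)
  expect_true(all(s1$spans$start <= s1$spans$end))
  expect_true(all(diff(s1$spans$start) > 0))
  expect_true(all(s1$spans$end <= nrow(s1$features)))
  expect_true(all(s1$spans$end[-20] < s1$spans$start[-1]))
  expect_true(all(s1$features >= 0))
  expect_equal(nrow(s1$features), length(s1$frame_labels))

  # noiseless features recover labels by nearest tuning column
  cfg0 <- small_config(noise_sd = 0)
  s0 <- synthesize_session(corpus[1:5], lex, tun, cfg0, seed = 3)
  mu <- sweep(tun$gain, 1, tun$baseline, "+")
  d2 <- outer(rowSums(s0$features^2), rep(1, ncol(mu))) -
    2 * s0$features %*% mu + outer(rep(1, nrow(s0$features)), colSums(mu^2))
  expect_equal(max.col(-d2), s0$frame_labels)

  # expected SIL fraction (ratio of expected counts): closed form vs
  # Monte-Carlo over 100 seeds
  words <- c("cat", "tea")   # 3 + 2 phonemes
  m <- cfg$frames_per_phoneme_mean
  sil <- cfg$sil_frames
  expected <- sil * 3 / (sil * 3 + 5 * m)
  tal <- vapply(1:300, function(s) {
    tr <- synthesize_trial(words, lex, tun, cfg, seed = 100 + s)
    c(sum(tr$frame_labels == sil_id(test_inv)), length(tr$frame_labels))
  }, c(0, 0))
  expect_equal(sum(tal[1, ]) / sum(tal[2, ]), expected, tolerance = 0.05)
})

test_that("session round-trips through the plain-text container", {
  cfg <- small_config()
  tun <- build_tuning(test_inv, cfg, seed = 4)
  lex <- tiny_lexicon()
  ses <- synthesize_session(c("hi cat", "a tea"), lex, tun, cfg,
                            day = 3L, seed = 5)
  path <- withr::local_tempdir()
  write_session(ses, file.path(path, "s"))
  back <- read_session(file.path(path, "s"), config = cfg)
  expect_equal(back$features, ses$features, tolerance = 1e-8)
  expect_identical(back$frame_labels, ses$frame_labels)
  expect_identical(back$transcripts, ses$transcripts)
  expect_equal(back$spans, ses$spans)
  expect_identical(back$day, 3L)
})
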