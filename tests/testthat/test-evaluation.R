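test_that("alignment worked examples", {
  id <- align_sequences(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(id$counts$S + id$counts$D + id$counts$I, 0)
  expect_equal(id$counts$N, 3L)

  del <- align_sequences(c("the", "quick", "fox"), c("the", "fox"))
  expect_equal(del$counts$D, 1)
  expect_equal(error_rate(del$counts), 1 / 3)
  expect_identical(del$ops$op, c("match", "del", "match"))

  ins <- align_sequences(character(0), c("a", "b"))
  expect_equal(ins$counts$I, 2)
  expect_equal(ins$counts$N, 0L)
  expect_error(error_rate(ins$counts), "undefined")
})

test_that("edit distance is a metric and matches the recursive oracle", {
  set.seed(5)
  syms <- c("x", "y", "z")
  rand_seq <- function() sample(syms, sample(0:8, 1), replace = TRUE)
  dist_of <- function(a, b) {
    cc <- align_sequences(a, b, details = FALSE)$counts
    cc$S + cc$D + cc$I
  }
  for (rep in 1:200) {
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    dab <- dist_of(a, b)
    expect_equal(dab, recursive_edit_distance(a, b))
    expect_equal(dist_of(a, a), 0)
    expect_equal(dab, dist_of(b, a))                        # symmetry
    expect_lte(dab, dist_of(a, c) + dist_of(c, b))          # triangle
  }
})

test_that("micro aggregation pools counts, macro would not", {
  c1 <- error_counts(S = 1, N = 10)
  c2 <- error_counts(N = 90)
  expect_equal(error_rate(list(c1, c2)), 0.01)
  expect_equal(error_rate(error_counts(S = 1, N = 50)), 0.02)
  expect_equal(error_rate(error_counts(I = 3, N = 1)), 3)

  # splitting into blocks leaves the pooled session rate unchanged
  set.seed(9)
  cs <- lapply(1:30, function(i)
    error_counts(S = rpois(1, 1), D = rpois(1, 0.5), I = rpois(1, 0.2),
                 N = sample(5:12, 1)))
  whole <- error_rate(cs)
  blocks <- split(cs, rep(1:5, each = 6))
  pooled <- error_rate(unlist(blocks, recursive = FALSE))
  expect_equal(pooled, whole)
})

test_that("bootstrap CI: degenerate cases and basic properties", {
  same <- lapply(1:10, function(i) error_counts(S = 1, N = 10))
  ci <- bootstrap_ci(same, n_resamples = 200, seed = 3)
  expect_equal(ci$lower, 0.1)
  expect_equal(ci$upper, 0.1)
  expect_equal(ci$point, 0.1)

  one <- bootstrap_ci(list(error_counts(S = 2, N = 8)), n_resamples = 100,
                      seed = 4)
  expect_equal(one$lower, one$point)
  expect_equal(one$upper, one$point)

  expect_error(bootstrap_ci(list()), "at least 1")

  set.seed(6)
  mixed <- lapply(1:40, function(i)
    error_counts(S = rbinom(1, 10, 0.1), N = 10))
  ci2 <- bootstrap_ci(mixed, n_resamples = 500, seed = 7)
  expect_lte(ci2$lower, ci2$point)
  expect_gte(ci2$upper, ci2$point)
  # determinism
  ci3 <- bootstrap_ci(mixed, n_resamples = 500, seed = 7)
  expect_equal(ci2$lower, ci3$lower)
  expect_equal(ci2$upper, ci3$upper)
})

test_that("bootstrap CI width shrinks with more sentences", {
  gen <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) error_counts(S = rbinom(1, 10, 0.05),
                                                N = 10))
  }
  small <- bootstrap_ci(gen(10, 1), n_resamples = 1000, seed = 2)
  big <- bootstrap_ci(gen(1000, 1), n_resamples = 1000, seed = 2)
  expect_lt(big$upper - big$lower, small$upper - small$lower)
})

test_that("confusion matrix tallies and articulatory ratio", {
  al0 <- align_sequences(c("K", "AE", "T"), c("K", "AE", "T"))
  cm0 <- phoneme_confusion(list(al0), test_inv)
  expect_equal(cm0$n_substitutions, 0L)
  expect_true(is.na(cm0$within_class_ratio))
  expect_equal(sum(cm0$matrix) - sum(diag(cm0$matrix)), 0)
  expect_equal(cm0$matrix["K", "K"], 1L)

  # constructed same-manner confusions (stops with stops) recover ratio > 1
  set.seed(8)
  stops <- c("B", "P", "D", "T", "G", "K")
  als <- lapply(1:60, function(i) {
    ref <- sample(c(stops, "AA", "IY", "S", "M"), 6, replace = TRUE)
    hyp <- ref
    k <- sample(6, 1)
    hyp[k] <- if (ref[k] %in% stops) sample(setdiff(stops, ref[k]), 1)
              else sample(setdiff(c("AA", "IY"), ref[k]), 1)
    align_sequences(ref, hyp)
  })
  cm <- phoneme_confusion(als, test_inv)
  expect_gt(cm$within_class_ratio, 1)
  expect_equal(cm$n_substitutions,
               sum(cm$matrix) - sum(diag(cm$matrix)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, p)
  expect_true(file.exists(p))
})

test_that("word error vs training count analysis", {
  res0 <- data.frame(reference = c("a b", "b c"), hypothesis = c("a b", "b c"))
  wf0 <- word_error_vs_training_count(res0, c("a b", "b"))
  expect_true(is.na(wf0$spearman_rho))
  expect_true(all(wf0$table$errors == 0))

  # rare words made systematically harder: negative rank correlation between
  # training count and accuracy means positive between count and error rate
  set.seed(10)
  words <- paste0("w", 1:8)
  train <- unlist(lapply(seq_along(words), function(i)
    rep(words[i], 2^(i - 1))))
  res <- do.call(rbind, lapply(1:200, function(i) {
    w <- sample(words, 1, prob = rev(seq_along(words)))
    err_p <- 0.75 * (1 - match(w, words) / 9)
    hyp <- if (runif(1) < err_p) "xx" else w
    data.frame(reference = w, hypothesis = hyp)
  }))
  wf <- word_error_vs_training_count(res, paste(train, collapse = " "))
  expect_lt(wf$spearman_rho, 0)

  # novel words (absent from training) fall into the zero bin
  res_novel <- data.frame(reference = "novelword", hypothesis = "novelword")
  wf2 <- word_error_vs_training_count(rbind(res, res_novel),
                                      paste(train, collapse = " "))
  expect_equal(wf2$table$training_count[wf2$table$word == "novelword"], 0L)
})

test_that("words per minute arithmetic", {
  expect_equal(words_per_minute(60, 1500), 30)
  expect_true(is.na(words_per_minute(10, 0)))
})

test_that("session report: confirmed fraction and empty logs", {
  log <- data.frame(self_report = c(rep("correct", 925),
                                    rep("incorrect", 1189 - 925)))
  rep1 <- session_report(conversation_log = log)
  expect_equal(round(100 * rep1$conversation$confirmed_fraction, 1), 77.8)
  expect_equal(rep1$conversation$n_total, 1189L)

  # no-report sentences excluded from the reported breakdown only
  log2 <- data.frame(self_report = c(rep("correct", 6), rep("incorrect", 2),
                                     rep("none", 2)))
  rep2 <- session_report(conversation_log = log2)
  expect_equal(rep2$conversation$confirmed_fraction, 0.6)
  expect_equal(rep2$conversation$reported_correct_fraction, 0.75)

  rep3 <- session_report(conversation_log = log2[0, , drop = FALSE])
  expect_equal(rep3$conversation$n_total, 0L)
  expect_true(is.na(rep3$conversation$confirmed_fraction))

  res <- data.frame(reference = c("a b c", "d e"),
                    hypothesis = c("a b c", "d x"),
                    frames = c(100L, 50L))
  rep4 <- session_report(res, n_resamples = 200, seed = 1)
  expect_equal(rep4$wer, 0.2)
  expect_equal(rep4$words_per_minute, words_per_minute(5, 150))
})
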