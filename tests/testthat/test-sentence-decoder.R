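test_that("collapse_path merges repeats and drops silence", {
  expect_identical(collapse_path(c("SIL", "HH", "HH", "AY", "SIL", "SIL")),
                   c("HH", "AY"))
  expect_identical(collapse_path(rep("SIL", 6)), character(0))
  expect_identical(collapse_path(c("K", "K", "AE", "AE", "T")),
                   c("K", "AE", "T"))
  expect_identical(collapse_path(character(0)), character(0))
  expect_identical(collapse_path(phoneme_id(test_inv, c("K", "K", "AE")),
                                 test_inv), c("K", "AE"))
})

test_that("forced one-hot decoding and homophone tie-breaking", {
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  lmu <- train_ngram(paste(vocab), order = 1, vocabulary = vocab)
  lp <- one_hot_logprobs(c("SIL", "HH", "AY", "SIL"))
  res <- beam_search(lp, lex, lmu, beam_config(), test_inv)
  # "hi" and "high" share the pronunciation; uniform LM -> lexicographic
  expect_identical(res$words, "hi")
  expect_identical(res$n_best$words[1:2], c("hi", "high"))
  expect_equal(res$n_best$total_score[1], res$n_best$total_score[2])
  # path invariant: collapsed path equals the pronunciation
  expect_identical(collapse_path(res$phoneme_path), c("HH", "AY"))
})

test_that("degenerate inputs: zero frames, empty lexicon, max_words 0", {
  lex <- tiny_lexicon()
  lm <- train_ngram("a at cat", order = 1, vocabulary = vocabulary(lex))
  res <- beam_search(matrix(0, 0, 40), lex, lm, beam_config(), test_inv)
  expect_identical(res$words, character(0))
  expect_equal(res$total_score, 0)
  expect_error(beam_search(uniform_logprobs(3), structure(list(),
                                                          class = "lexicon"),
                           lm, beam_config(), test_inv), "empty lexicon")
  # max_words 0: empty sequence, acoustic score of the all-SIL path
  lp <- uniform_logprobs(5)
  ex <- exhaustive_decode(lp, lex, lm, max_words = 0,
                          beam_config(lm_weight = 0), test_inv)
  expect_identical(ex$words, character(0))
  expect_equal(ex$acoustic_score, sum(lp[, sil_id(test_inv)]))
  expect_error(exhaustive_decode(lp, lex, lm, max_words = 10,
                                 beam_config(), test_inv), "guard")
})

test_that("beam search equals the exhaustive oracle on random instances", {
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  lm <- train_ngram(make_corpus(vocab, 30, seed = 5), order = 2,
                    vocabulary = vocab)
  set.seed(101)
  for (rep in 1:20) {
    Tn <- sample(6:12, 1)
    lp <- matrix(rnorm(Tn * 40), Tn, 40)
    lp <- lp - log(rowSums(exp(lp)))
    cfg <- beam_config(beam_width = 5000L, n_best = 5L,
                       lm_weight = runif(1, 0.5, 1.5),
                       word_insertion_bonus = runif(1, -0.5, 0.5),
                       max_words = 3)
    b <- beam_search(lp, lex, lm, cfg, test_inv)
    e <- exhaustive_decode(lp, lex, lm, max_words = 3, cfg, test_inv)
    expect_identical(b$words, e$words)
    expect_equal(b$total_score, e$total_score, tolerance = 1e-9)
  }
})

test_that("widening the beam improves the search towards the optimum", {
  # The saturating beam dominates every narrower run (its winner is the
  # global optimum). Between narrow widths monotonicity holds in the vast
  # majority of cases but is not guaranteed: pruned hypothesis sets are not
  # nested across widths, so occasional inversions at very small beams are
  # inherent to beam pruning.
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  lm <- train_ngram(make_corpus(vocab, 30, seed = 6), order = 2,
                    vocabulary = vocab)
  set.seed(202)
  n_steps <- 0L
  n_monotone <- 0L
  for (rep in 1:10) {
    Tn <- sample(8:14, 1)
    lp <- matrix(rnorm(Tn * 40), Tn, 40)
    lp <- lp - log(rowSums(exp(lp)))
    widths <- c(1L, 2L, 4L, 16L, 64L, 512L)
    scores <- vapply(widths, function(w)
      beam_search(lp, lex, lm, beam_config(beam_width = w, n_best = 1L),
                  test_inv)$total_score, 0)
    expect_true(all(scores <= scores[length(scores)] + 1e-9))
    d <- diff(scores)
    n_steps <- n_steps + length(d)
    n_monotone <- n_monotone + sum(d >= -1e-9)
  }
  expect_gte(n_monotone / n_steps, 0.85)
})

test_that("raising the LM weight never lowers the winner's LM score", {
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  lm <- train_ngram(make_corpus(vocab, 30, seed = 7), order = 2,
                    vocabulary = vocab)
  set.seed(303)
  for (rep in 1:5) {
    lp <- matrix(rnorm(10 * 40), 10, 40)
    lp <- lp - log(rowSums(exp(lp)))
    alphas <- c(0.25, 0.5, 1, 2, 4)
    lm_scores <- vapply(alphas, function(a)
      beam_search(lp, lex, lm, beam_config(lm_weight = a), test_inv)$lm_score,
      0)
    expect_true(all(diff(lm_scores) >= -1e-9))
  }
})

test_that("n-best rescoring: identity at weight 0, constructed swap, stability", {
  lex <- tiny_lexicon()
  vocab <- vocabulary(lex)
  lmu <- train_ngram(paste(vocab), order = 1, vocabulary = vocab)
  lp <- one_hot_logprobs(c("SIL", "HH", "AY", "SIL"))
  res <- beam_search(lp, lex, lmu, beam_config(), test_inv)
  expect_identical(res$n_best$words[1:2], c("hi", "high"))

  same <- rescore_nbest(res, lmu, weight = 0)
  expect_identical(same$n_best$words, res$n_best$words)
  expect_identical(same$words, res$words)

  # a rescoring LM that has only ever seen "high" swaps the homophones
  lm_high <- train_ngram(rep("high", 10), order = 1, vocabulary = vocab)
  sw <- rescore_nbest(res, lm_high, weight = 1, lexicon = lex,
                      frame_logprobs = lp, inventory = test_inv)
  expect_identical(sw$words, "high")
  expect_identical(collapse_path(sw$phoneme_path), c("HH", "AY"))

  one <- res
  one$n_best <- one$n_best[1, , drop = FALSE]
  expect_identical(rescore_nbest(one, lm_high)$n_best$words[1],
                   one$n_best$words[1])
  empty <- res
  empty$n_best <- empty$n_best[0, , drop = FALSE]
  expect_identical(rescore_nbest(empty, lm_high)$words, res$words)
})

test_that("single-word vocabulary decodes to that word or silence", {
  inv <- test_inv
  lex <- read_lexicon("CAT K AE1 T", inv)
  lm <- train_ngram("cat", order = 1, vocabulary = "cat")
  lp <- one_hot_logprobs(c("K", "AE", "T"))
  res <- exhaustive_decode(lp, lex, lm, max_words = 2, beam_config(), inv)
  expect_identical(res$words, "cat")
  b <- beam_search(lp, lex, lm, beam_config(), inv)
  expect_identical(b$words, "cat")
})
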