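#' Beam-search configuration
#'
#' @param beam_width maximum hypotheses kept per frame (>= 1).
#' @param lm_weight language-model weight (alpha) on the in-beam LM score.
#' @param word_insertion_bonus additive bonus (beta) per emitted word.
#' @param n_best number of alternates returned (<= beam_width).
#' @param max_words cap on the number of emitted words (`Inf` by default;
#'   finite values make the search directly comparable to
#'   [exhaustive_decode()]).
#' @return object of class `beam_config`.
#' @export
beam_config <- function(beam_width = 64L, lm_weight = 1,
                        word_insertion_bonus = 0,
                        n_best = min(10L, beam_width),
                        max_words = Inf) {
  if (beam_width < 1) stop_config("beam_width must be >= 1")
  if (n_best > beam_width) stop_config("n_best must be <= beam_width")
  structure(list(beam_width = as.integer(beam_width), lm_weight = lm_weight,
                 word_insertion_bonus = word_insertion_bonus,
                 n_best = as.integer(n_best), max_words = max_words),
            class = "beam_config")
}

#' Collapse a frame-level phoneme path
#'
#' Merges consecutive repeats and removes silence, turning a frame-aligned
#' label sequence into a phoneme sequence.
#'
#' @param frame_phonemes character vector of phoneme labels (or integer ids,
#'   with `inventory` given).
#' @param inventory optional [phoneme_inventory()] when ids are passed.
#' @return character vector of phonemes (possibly empty).
#' @export
collapse_path <- function(frame_phonemes, inventory = NULL) {
  if (is.numeric(frame_phonemes)) {
    stopifnot(!is.null(inventory))
    frame_phonemes <- inventory$symbols[frame_phonemes]
  }
  if (length(frame_phonemes) == 0) return(character(0))
  r <- rle(frame_phonemes)$values
  r[r != SIL]
}

# Compile lexicon + inventory into a pronunciation prefix tree with flat
# arrays (fast vectorized expansion in the beam search).
# Node 0 is the silence/start state; tree nodes are 1..M.
compile_decode_graph <- function(lexicon, inventory) {
  if (length(lexicon) == 0) stop_config("empty lexicon")
  words <- sort(names(lexicon))
  node_phone <- integer(0)          # phoneme id per node
  node_children <- list()           # phoneme-id -> child-node maps
  node_words <- list()              # word indices ending at node
  children_of <- list(root = integer(0))
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  root_children <- new.env(hash = TRUE, parent = emptyenv())
  new_node <- function(phone) {
    node_phone[[length(node_phone) + 1L]] <<- phone
    node_words[[length(node_phone)]] <<- integer(0)
    node_children[[length(node_phone)]] <<- integer(0)
    length(node_phone)
  }
  for (wi in seq_along(words)) {
    for (pron in lexicon[[words[wi]]]) {
      ids <- phoneme_id(inventory, pron)
      cur <- 0L
      for (ph in ids) {
        key <- paste0(cur, ":", ph)
        nxt <- key_env[[key]]
        if (is.null(nxt)) {
          nxt <- new_node(ph)
          key_env[[key]] <- nxt
          if (cur == 0L) {
            children_of$root <- c(children_of$root, nxt)
          } else {
            node_children[[cur]] <- c(node_children[[cur]], nxt)
          }
        }
        cur <- nxt
      }
      node_words[[cur]] <- c(node_words[[cur]], wi)
    }
  }
  M <- length(node_phone)
  # flatten children (index node+1; entry 1 = root)
  ch_lists <- c(list(children_of$root), node_children)
  child_cnt <- lengths(ch_lists)
  child_off <- c(0L, cumsum(child_cnt))[seq_along(ch_lists)]
  child_flat <- unlist(ch_lists, use.names = FALSE)
  wend_cnt <- lengths(node_words)
  wend_off <- c(0L, cumsum(wend_cnt))[seq_len(M)]
  wend_flat <- unlist(node_words, use.names = FALSE)
  list(words = words, n_nodes = M,
       node_phone = as.integer(node_phone),
       child_cnt = as.integer(child_cnt), child_off = as.integer(child_off),
       child_flat = as.integer(child_flat %||% integer(0)),
       wend_cnt = as.integer(wend_cnt), wend_off = as.integer(wend_off),
       wend_flat = as.integer(wend_flat %||% integer(0)),
       sil = sil_id(inventory))
}

graph_children <- function(g, node) {
  # node may be 0 (root/silence)
  i <- node + 1L
  if (g$child_cnt[i] == 0L) integer(0)
  else g$child_flat[g$child_off[i] + seq_len(g$child_cnt[i])]
}

# LM context tokens from the last-two-words representation.
ctx_tokens <- function(last2, last1, order) {
  if (order <= 1) return(character(0))
  if (order == 2 || last2 == "") {
    if (last1 == "") character(0) else last1
  } else c(last2, last1)
}

#' Lexicon- and LM-constrained beam search
#'
#' Time-synchronous Viterbi beam search over a pronunciation prefix tree of
#' the vocabulary. Each frame a hypothesis may stay in its phoneme, advance
#' along the tree, or (at a word end) emit the word — paying the weighted
#' language-model cost plus the word-insertion bonus — and either pass
#' through optional silence or begin the next word directly. Hypotheses are
#' merged by (tree position, word history) keeping the best alignment, and
#' pruned to `beam_width`. Deterministic; score ties are broken
#' lexicographically by word sequence.
#'
#' @param frame_logprobs frames x phonemes matrix of log-probabilities
#'   (rows normalized).
#' @param lexicon a `lexicon`.
#' @param lm an `ngram_lm`; lexicon words should be inside its vocabulary.
#' @param config a [beam_config()].
#' @param inventory the [phoneme_inventory()] indexing the columns.
#' @return object of class `decode_result`: `words`, `phoneme_path`,
#'   `acoustic_score`, `lm_score`, `total_score` and an `n_best` data frame.
#' @export
beam_search <- function(frame_logprobs, lexicon, lm, config = beam_config(),
                        inventory = phoneme_inventory()) {
  g <- compile_decode_graph(lexicon, inventory)
  Tn <- nrow(frame_logprobs)
  if (is.null(Tn) || Tn == 0) {
    return(empty_decode_result())
  }
  alpha <- config$lm_weight
  beta <- config$word_insertion_bonus
  order <- lm$order

  # hypothesis vectors
  root_kids <- graph_children(g, 0L)
  hyp_node <- c(0L, root_kids)
  hyp_hist <- rep("", length(hyp_node))
  hyp_last1 <- rep("<s>", length(hyp_node))
  hyp_last2 <- rep("", length(hyp_node))
  hyp_nw <- integer(length(hyp_node))
  phone1 <- ifelse(hyp_node == 0L, g$sil, g$node_phone[pmax(hyp_node, 1L)])
  hyp_score <- frame_logprobs[1L, phone1]

  for (t in seq_len(Tn)[-1]) {
    # --- stay ---
    c_node <- hyp_node; c_score <- hyp_score
    c_hist <- hyp_hist; c_l1 <- hyp_last1; c_l2 <- hyp_last2
    c_nw <- hyp_nw
    # --- advance along tree (word starts blocked at the max_words cap) ---
    nch <- g$child_cnt[hyp_node + 1L]
    nch[hyp_node == 0L & hyp_nw >= config$max_words] <- 0L
    adv <- which(nch > 0L)
    if (length(adv)) {
      src <- rep.int(adv, nch[adv])
      kid <- unlist(lapply(adv, function(i)
        graph_children(g, hyp_node[i])), use.names = FALSE)
      c_node <- c(c_node, kid)
      c_score <- c(c_score, hyp_score[src])
      c_hist <- c(c_hist, hyp_hist[src])
      c_l1 <- c(c_l1, hyp_last1[src])
      c_l2 <- c(c_l2, hyp_last2[src])
      c_nw <- c(c_nw, hyp_nw[src])
    }
    # --- word emission at word-end nodes ---
    at_end <- which(hyp_node > 0L & g$wend_cnt[pmax(hyp_node, 1L)] > 0L)
    if (length(at_end)) {
      src <- rep.int(at_end, g$wend_cnt[hyp_node[at_end]])
      wid <- unlist(lapply(at_end, function(i) {
        nd <- hyp_node[i]
        g$wend_flat[g$wend_off[nd] + seq_len(g$wend_cnt[nd])]
      }), use.names = FALSE)
      wtok <- g$words[wid]
      ctxs <- lapply(src, function(i)
        ctx_tokens(hyp_last2[i], hyp_last1[i], order))
      lmcost <- alpha * ngram_logprob_batch(lm, ctxs, wtok) + beta
      e_score <- hyp_score[src] + lmcost
      e_hist <- ifelse(hyp_hist[src] == "", wtok,
                       paste(hyp_hist[src], wtok))
      e_l2 <- hyp_last1[src]
      e_l1 <- wtok
      e_nw <- hyp_nw[src] + 1L
      # next states: silence always; a new word only below the cap
      n_e <- length(e_score)
      can_start <- e_nw < config$max_words
      nxt_cnt <- ifelse(can_start, 1L + length(root_kids), 1L)
      rep_e <- rep.int(seq_len(n_e), nxt_cnt)
      nxt <- unlist(lapply(seq_len(n_e), function(j)
        if (can_start[j]) c(0L, root_kids) else 0L), use.names = FALSE)
      c_node <- c(c_node, nxt)
      c_score <- c(c_score, e_score[rep_e])
      c_hist <- c(c_hist, e_hist[rep_e])
      c_l1 <- c(c_l1, e_l1[rep_e])
      c_l2 <- c(c_l2, e_l2[rep_e])
      c_nw <- c(c_nw, e_nw[rep_e])
    }
    # --- acoustic score of the consumed frame ---
    phone_t <- ifelse(c_node == 0L, g$sil, g$node_phone[pmax(c_node, 1L)])
    c_score <- c_score + frame_logprobs[t, phone_t]
    # --- merge by (node, history): keep best alignment ---
    key <- paste0(c_node, "|", c_hist)
    ord <- order(key, -c_score, method = "radix")
    keep <- ord[!duplicated(key[ord])]
    # --- prune to beam width (ties: lexicographic word sequence) ---
    ord2 <- order(-c_score[keep], c_hist[keep], method = "radix")
    keep <- keep[ord2[seq_len(min(length(ord2), config$beam_width))]]
    hyp_node <- c_node[keep]; hyp_score <- c_score[keep]
    hyp_hist <- c_hist[keep]; hyp_last1 <- c_l1[keep]; hyp_last2 <- c_l2[keep]
    hyp_nw <- c_nw[keep]
  }

  # --- finalization: complete the word in progress, add end-of-sentence ---
  fin_hist <- character(0); fin_score <- numeric(0)
  in_sil <- which(hyp_node == 0L)
  if (length(in_sil)) {
    ctxs <- lapply(in_sil, function(i)
      ctx_tokens(hyp_last2[i], hyp_last1[i], order))
    fin_score <- hyp_score[in_sil] +
      alpha * ngram_logprob_batch(lm, ctxs, rep(TOK_EOS, length(in_sil)))
    fin_hist <- hyp_hist[in_sil]
  }
  at_end <- which(hyp_node > 0L & g$wend_cnt[pmax(hyp_node, 1L)] > 0L)
  if (length(at_end)) {
    src <- rep.int(at_end, g$wend_cnt[hyp_node[at_end]])
    wid <- unlist(lapply(at_end, function(i) {
      nd <- hyp_node[i]
      g$wend_flat[g$wend_off[nd] + seq_len(g$wend_cnt[nd])]
    }), use.names = FALSE)
    wtok <- g$words[wid]
    ctx1 <- lapply(src, function(i)
      ctx_tokens(hyp_last2[i], hyp_last1[i], order))
    lm_w <- ngram_logprob_batch(lm, ctx1, wtok)
    ctx2 <- lapply(seq_along(src), function(j)
      ctx_tokens(hyp_last1[src[j]], wtok[j], order))
    lm_end <- ngram_logprob_batch(lm, ctx2, rep(TOK_EOS, length(src)))
    fin_score <- c(fin_score,
                   hyp_score[src] + alpha * (lm_w + lm_end) + beta)
    fin_hist <- c(fin_hist, ifelse(hyp_hist[src] == "", wtok,
                                   paste(hyp_hist[src], wtok)))
  }
  if (length(fin_score) == 0) {
    # no completable hypothesis survived (degenerate beam): fall back to
    # the empty sequence scored on the all-silence path
    return(scored_result(character(0), frame_logprobs, lexicon, lm, config,
                         inventory, n_best_hists = character(0)))
  }
  ord <- order(-fin_score, fin_hist, method = "radix")
  fin_score <- fin_score[ord]; fin_hist <- fin_hist[ord]
  keep <- !duplicated(fin_hist)
  fin_score <- fin_score[keep]; fin_hist <- fin_hist[keep]
  nb <- utils::head(fin_hist, config$n_best)
  best_words <- if (fin_hist[1] == "") character(0)
                else strsplit(fin_hist[1], " ", fixed = TRUE)[[1]]
  scored_result(best_words, frame_logprobs, lexicon, lm, config, inventory,
                n_best_hists = nb, internal_total = fin_score[1])
}

empty_decode_result <- function() {
  structure(list(words = character(0), phoneme_path = character(0),
                 acoustic_score = 0, lm_score = 0, total_score = 0,
                 n_best = data.frame(words = character(0),
                                     acoustic_score = numeric(0),
                                     lm_score = numeric(0),
                                     total_score = numeric(0))),
            class = "decode_result")
}

# Build a decode_result for a word sequence: forced alignment for the
# phoneme path and acoustic score, LM score, and the n-best table.
scored_result <- function(words, frame_logprobs, lexicon, lm, config,
                          inventory, n_best_hists, internal_total = NULL) {
  al <- align_words_to_frames(words, frame_logprobs, lexicon, inventory)
  lm_sc <- sequence_logprob_invocab(lm, words)
  total <- al$score + config$lm_weight * lm_sc +
    config$word_insertion_bonus * length(words)
  nb <- score_hypotheses(n_best_hists, frame_logprobs, lexicon, lm, config,
                         inventory)
  structure(list(words = words,
                 phoneme_path = inventory$symbols[al$path],
                 acoustic_score = al$score, lm_score = lm_sc,
                 total_score = total, n_best = nb),
            class = "decode_result")
}

# sequence_logprob without the OOV mapping (decoder output words are always
# in the lexicon; mapping to <unk> here would double-count probability mass).
sequence_logprob_invocab <- function(lm, words) {
  toks <- c(TOK_BOS, words, TOK_EOS)
  total <- 0
  for (i in 2:length(toks)) {
    start <- max(1, i - lm$order + 1)
    ctx <- if (start > i - 1) character(0) else toks[start:(i - 1)]
    total <- total + ngram_logprob(lm, ctx, toks[i])
  }
  total
}

score_hypotheses <- function(hists, frame_logprobs, lexicon, lm, config,
                             inventory) {
  if (length(hists) == 0) {
    return(data.frame(words = character(0), acoustic_score = numeric(0),
                      lm_score = numeric(0), total_score = numeric(0)))
  }
  rows <- lapply(hists, function(h) {
    ws <- if (h == "") character(0) else strsplit(h, " ", fixed = TRUE)[[1]]
    al <- align_words_to_frames(ws, frame_logprobs, lexicon, inventory)
    lm_sc <- sequence_logprob_invocab(lm, ws)
    data.frame(words = h, acoustic_score = al$score, lm_score = lm_sc,
               total_score = al$score + config$lm_weight * lm_sc +
                 config$word_insertion_bonus * length(ws),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> \"%s\" (total %.3f = acoustic %.3f + lm %.3f)\n",
              paste(x$words, collapse = " "), x$total_score,
              x$acoustic_score, x$lm_score))
  invisible(x)
}

# Force-align a word sequence to frame log-probabilities: optional silence at
# the boundaries and between words, every phoneme >= 1 frame. Handles
# multiple pronunciations by taking the best combination (guarded).
# Returns list(score = best acoustic log-probability, path = frame ids).
align_words_to_frames <- function(words, frame_logprobs, lexicon, inventory) {
  Tn <- nrow(frame_logprobs)
  sid <- sil_id(inventory)
  if (length(words) == 0) {
    return(list(score = sum(frame_logprobs[, sid]),
                path = rep(sid, Tn)))
  }
  pron_sets <- lapply(words, function(w) lexicon_pron(lexicon, w, all = TRUE))
  n_comb <- prod(lengths(pron_sets))
  if (n_comb > 64) pron_sets <- lapply(pron_sets, function(p) p[1])
  combos <- expand.grid(lapply(pron_sets, seq_along))
  best <- list(score = -Inf, path = NULL)
  for (ci in seq_len(nrow(combos))) {
    phones <- integer(0); optional <- logical(0)
    phones <- c(phones, sid); optional <- c(optional, TRUE)
    for (wi in seq_along(words)) {
      ids <- phoneme_id(inventory, pron_sets[[wi]][[combos[ci, wi]]])
      phones <- c(phones, ids); optional <- c(optional, rep(FALSE, length(ids)))
      phones <- c(phones, sid); optional <- c(optional, TRUE)
    }
    r <- viterbi_align(frame_logprobs, phones, optional)
    if (r$score > best$score) best <- r
  }
  best
}

# Linear-chain Viterbi with optional (skippable) states; each entered state
# emits >= 1 frame. Returns best score and per-frame state phoneme ids.
viterbi_align <- function(frame_logprobs, phones, optional) {
  Tn <- nrow(frame_logprobs)
  S <- length(phones)
  n_mand <- sum(!optional)
  if (n_mand > Tn) return(list(score = -Inf, path = NULL))
  # predecessor sets: from s' to s if s' < s and all states between optional
  preds <- lapply(seq_len(S), function(s) {
    out <- integer(0)
    s2 <- s - 1L
    while (s2 >= 1L) {
      out <- c(out, s2)
      if (!optional[s2]) break
      s2 <- s2 - 1L
    }
    out
  })
  entry <- logical(S)
  for (s in seq_len(S)) {
    entry[s] <- all(optional[seq_len(s - 1L)])
    if (s > 1L && !entry[s - 1L] && !optional[s - 1L]) break
  }
  exit <- vapply(seq_len(S), function(s)
    s == S || all(optional[(s + 1L):S]), TRUE)
  V <- matrix(-Inf, Tn, S)
  B <- matrix(0L, Tn, S)
  V[1, entry] <- frame_logprobs[1, phones[entry]]
  for (t in 2:Tn) {
    if (Tn < 2) break
    for (s in seq_len(S)) {
      cand <- c(s, preds[[s]])
      vals <- V[t - 1L, cand]
      j <- which.max(vals)
      if (is.finite(vals[j])) {
        V[t, s] <- vals[j] + frame_logprobs[t, phones[s]]
        B[t, s] <- cand[j]
      }
    }
  }
  fin <- which(exit)
  s_best <- fin[which.max(V[Tn, fin])]
  if (!is.finite(V[Tn, s_best])) return(list(score = -Inf, path = NULL))
  path <- integer(Tn)
  s <- s_best
  for (t in Tn:1) {
    path[t] <- phones[s]
    if (t > 1L) s <- B[t, s]
  }
  list(score = V[Tn, s_best], path = path)
}

#' Exhaustive decoding oracle
#'
#' Enumerates every word sequence up to `max_words` (in lexicographic
#' order), force-aligns each to the frames, and returns the argmax of the
#' combined score — the brute-force reference the beam search is tested
#' against.
#'
#' @inheritParams beam_search
#' @param max_words maximum sequence length; `|vocabulary|^max_words` must
#'   not exceed 1e5.
#' @return a `decode_result`.
#' @export
exhaustive_decode <- function(frame_logprobs, lexicon, lm, max_words,
                              config = beam_config(),
                              inventory = phoneme_inventory()) {
  words <- sort(names(lexicon))
  if (length(words)^max_words > 1e5) {
    stop_config("exhaustive_decode guard: |V|^max_words > 1e5")
  }
  Tn <- nrow(frame_logprobs)
  if (is.null(Tn) || Tn == 0) return(empty_decode_result())
  seqs <- list(character(0))
  frontier <- list(character(0))
  for (k in seq_len(max_words)) {
    frontier <- unlist(lapply(frontier, function(s)
      lapply(words, function(w) c(s, w))), recursive = FALSE)
    seqs <- c(seqs, frontier)
  }
  scores <- vapply(seqs, function(ws) {
    al <- align_words_to_frames(ws, frame_logprobs, lexicon, inventory)
    if (!is.finite(al$score)) return(-Inf)
    al$score + config$lm_weight * sequence_logprob_invocab(lm, ws) +
      config$word_insertion_bonus * length(ws)
  }, 0)
  ord <- order(-scores, vapply(seqs, paste, "", collapse = " "),
               method = "radix")
  nb_hists <- vapply(seqs[utils::head(ord, config$n_best)], paste, "",
                     collapse = " ")
  nb_hists <- nb_hists[is.finite(scores[utils::head(ord, config$n_best)])]
  best <- seqs[[ord[1]]]
  scored_result(best, frame_logprobs, lexicon, lm, config, inventory,
                n_best_hists = nb_hists)
}

#' Rescore the n-best list with a second language model
#'
#' Re-ranks the alternates by `acoustic_score + weight * lm2_score`; the
#' re-rank is stable (original order preserved on ties). The top hypothesis
#' after rescoring becomes the result's word sequence.
#'
#' @param result a `decode_result`.
#' @param lm2 the rescoring `ngram_lm` (typically higher order).
#' @param weight rescoring LM weight.
#' @param lexicon,frame_logprobs,inventory optional; when given, the
#'   phoneme path of a changed top hypothesis is re-aligned.
#' @return the rescored `decode_result`.
#' @export
rescore_nbest <- function(result, lm2, weight = 1, lexicon = NULL,
                          frame_logprobs = NULL,
                          inventory = phoneme_inventory()) {
  nb <- result$n_best
  if (nrow(nb) == 0) return(result)
  lm2_sc <- vapply(nb$words, function(h) {
    ws <- if (h == "") character(0) else strsplit(h, " ", fixed = TRUE)[[1]]
    sequence_logprob_invocab(lm2, ws)
  }, 0)
  new_total <- nb$acoustic_score + weight * lm2_sc
  ord <- order(-new_total)  # stable: ties keep original order
  nb <- nb[ord, , drop = FALSE]
  nb$lm2_score <- lm2_sc[ord]
  nb$rescored_total <- new_total[ord]
  rownames(nb) <- NULL
  out <- result
  out$n_best <- nb
  top <- nb$words[1]
  top_words <- if (top == "") character(0)
               else strsplit(top, " ", fixed = TRUE)[[1]]
  if (!identical(top_words, result$words)) {
    out$words <- top_words
    out$acoustic_score <- nb$acoustic_score[1]
    out$lm_score <- nb$lm_score[1]
    out$total_score <- nb$total_score[1]
    if (!is.null(lexicon) && !is.null(frame_logprobs)) {
      al <- align_words_to_frames(top_words, frame_logprobs, lexicon,
                                  inventory)
      out$phoneme_path <- inventory$symbols[al$path]
    } else {
      out$phoneme_path <- result$phoneme_path
    }
  }
  out
}
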