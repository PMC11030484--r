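# Special tokens of the language model.
TOK_BOS <- "<s>"
TOK_EOS <- "</s>"
TOK_UNK <- "<unk>"

# Conventional placeholder log10-probability for events that cannot occur
# (e.g. predicting <s>), and the floor returned for zero-probability events
# under unsmoothed maximum likelihood.
LOGP10_FLOOR <- -99
LOGP_FLOOR <- LOGP10_FLOOR * log(10)

#' Train a backoff n-gram language model
#'
#' Maximum-likelihood counts with Witten-Bell discounting and backoff (the
#' parameter-free default) or raw maximum likelihood (`"none"`, unseen events
#' floored). Corpus tokens outside the vocabulary are mapped to the unknown
#' token, so the model is defined over `vocabulary + </s> + <unk>` in every
#' context.
#'
#' @param corpus character vector of sentences (whitespace-separated words).
#' @param order n-gram order, 1 to 3.
#' @param vocabulary a [vocabulary()] (or character vector of words).
#' @param smoothing `"witten_bell"` (default) or `"none"`.
#' @return object of class `ngram_lm`.
#' @export
train_ngram <- function(corpus, order = 2L,
                        vocabulary = NULL,
                        smoothing = c("witten_bell", "none")) {
  smoothing <- match.arg(smoothing)
  stopifnot(order %in% 1:3)
  if (length(corpus) == 0) stop_config("corpus must be nonempty")
  sents <- strsplit(tolower(trimws(corpus)), "\\s+")
  if (is.null(vocabulary)) vocabulary <- vocabulary(unlist(sents))
  vocab <- sort(unique(tolower(as.character(vocabulary))))
  if (length(vocab) == 0) stop_config("empty vocabulary")
  events <- c(vocab, TOK_EOS, TOK_UNK)

  sents <- lapply(sents, function(s) {
    s[!(s %in% vocab)] <- TOK_UNK
    c(TOK_BOS, s, TOK_EOS)
  })

  count_k <- function(k) {
    grams <- unlist(lapply(sents, function(p) {
      L <- length(p)
      if (L < k) return(character(0))
      n <- L - k + 1
      out <- vapply(seq_len(n), function(i) paste(p[i:(i + k - 1)],
                                                  collapse = " "), "")
      out[p[k - 1 + seq_len(n)] != TOK_BOS]
    }))
    tab <- table(grams)
    stats::setNames(as.vector(tab), names(tab))
  }

  counts <- lapply(seq_len(order), count_k)

  lm <- structure(list(order = as.integer(order), smoothing = smoothing,
                       vocab = vocab, tables = vector("list", order)),
                  class = "ngram_lm")

  # --- unigrams ---------------------------------------------------------
  c1 <- counts[[1]]
  N <- sum(c1)
  T1 <- length(c1)
  p1 <- if (smoothing == "witten_bell") {
    cc <- c1[match(events, names(c1))]
    cc[is.na(cc)] <- 0
    cc / (N + T1) + (T1 / (N + T1)) / length(events)
  } else {
    cc <- c1[match(events, names(c1))]
    cc[is.na(cc)] <- 0
    ifelse(cc > 0, cc / N, exp(LOGP_FLOOR))
  }
  tab1 <- data.frame(ngram = c(events, TOK_BOS),
                     logp = c(unname(log(p1)), LOGP_FLOOR),
                     bow = 0, stringsAsFactors = FALSE)
  if (smoothing == "none") tab1 <- tab1[c(which(c1[match(events, names(c1))] > 0 |
                                                events == TOK_UNK), length(events) + 1L), ]
  lm$tables[[1]] <- tab1
  lm <- lm_rebuild_env(lm)

  # --- higher orders ----------------------------------------------------
  if (order >= 2) {
    for (k in 2:order) {
      ck <- counts[[k]]
      grams <- names(ck)
      parts <- strsplit(grams, " ", fixed = TRUE)
      ctx <- vapply(parts, function(p) paste(p[-k], collapse = " "), "")
      w <- vapply(parts, function(p) p[k], "")
      csum <- tapply(ck, ctx, sum)
      tdist <- tapply(rep(1L, length(ck)), ctx, sum)
      ch <- csum[ctx]
      th <- tdist[ctx]
      p <- if (smoothing == "witten_bell") ck / (ch + th) else ck / ch
      lm$tables[[k]] <- data.frame(ngram = grams, logp = log(p), bow = 0,
                                   stringsAsFactors = FALSE)
      lm <- lm_rebuild_env(lm)

      if (smoothing == "witten_bell") {
        # Backoff weights live on the (k-1)-gram rows of each seen context.
        ctx_names <- names(csum)
        sel_by_ctx <- split(seq_along(ctx), ctx)
        bow <- vapply(ctx_names, function(h) {
          sel <- sel_by_ctx[[h]]
          p_here <- sum(p[sel])
          hp <- strsplit(h, " ", fixed = TRUE)[[1]][-1]
          p_low <- sum(vapply(w[sel], function(wi)
            exp(ngram_logprob(lm, hp, wi)), 0))
          denom <- 1 - p_low
          if (denom <= 1e-12) return(0)  # every event seen: no mass to spread
          log((1 - p_here) / denom)
        }, 0)
        tabp <- lm$tables[[k - 1]]
        idx <- match(ctx_names, tabp$ngram)
        new_rows <- which(is.na(idx))
        if (length(new_rows)) {
          tabp <- rbind(tabp, data.frame(ngram = ctx_names[new_rows],
                                         logp = LOGP_FLOOR, bow = 0,
                                         stringsAsFactors = FALSE))
          idx <- match(ctx_names, tabp$ngram)
        }
        tabp$bow[idx] <- bow
        lm$tables[[k - 1]] <- tabp
        lm <- lm_rebuild_env(lm)
      }
    }
  }
  lm
}

# Rebuild the O(1) lookup environments from the tables.
lm_rebuild_env <- function(lm) {
  lm$logp_env <- lapply(lm$tables, function(tab) {
    if (is.null(tab)) return(NULL)
    e <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(tab) * 2L)
    for (i in seq_len(nrow(tab))) assign(tab$ngram[i], tab$logp[i], envir = e)
    e
  })
  lm$bow_env <- lapply(lm$tables, function(tab) {
    if (is.null(tab)) return(NULL)
    e <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(tab) * 2L)
    has <- which(tab$bow != 0)
    for (i in has) assign(tab$ngram[i], tab$bow[i], envir = e)
    e
  })
  lm
}

lm_lookup <- function(env, keys) {
  unlist(mget(keys, envir = env, ifnotfound = NA_real_), use.names = FALSE)
}

#' Conditional log-probability of one word
#'
#' Backoff query: the longest stored n-gram matching `(context, word)` is
#' used; otherwise the context's backoff weight is added and the context
#' shortened. Out-of-vocabulary words should be mapped to the unknown token
#' by the caller ([sequence_logprob()] does this).
#'
#' @param lm an `ngram_lm`.
#' @param context character vector of preceding tokens (may be empty).
#' @param word the predicted token.
#' @return natural log-probability (scalar).
#' @export
ngram_logprob <- function(lm, context, word) {
  keep <- lm$order - 1L
  if (length(context) > keep) {
    context <- if (keep == 0L) character(0) else
      context[(length(context) - keep + 1L):length(context)]
  }
  repeat {
    k <- length(context) + 1L
    key <- paste(c(context, word), collapse = " ")
    hit <- lm_lookup(lm$logp_env[[k]], key)
    if (!is.na(hit)) return(hit)
    if (k == 1L) return(LOGP_FLOOR)
    if (lm$smoothing == "none") return(LOGP_FLOOR)
    bw <- lm_lookup(lm$bow_env[[k - 1L]],
                    paste(context, collapse = " "))
    bw <- if (is.na(bw)) 0 else bw
    res <- bw + ngram_logprob(lm, context[-1], word)
    return(res)
  }
}

# Vectorized backoff query: contexts is a list of token vectors (already
# truncated to order-1), words a character vector of the same length.
ngram_logprob_batch <- function(lm, contexts, words) {
  vapply(seq_along(words), function(i)
    ngram_logprob(lm, contexts[[i]], words[i]), 0)
}

#' Log-probability of a word sequence
#'
#' Sum of conditional log-probabilities of every word given its history,
#' including the end-of-sentence token; OOV words are mapped to the unknown
#' token. The empty sequence scores `log P(</s> | <s>)`.
#'
#' @param lm an `ngram_lm`.
#' @param words character vector of words (or a single sentence string).
#' @return natural log-probability.
#' @export
sequence_logprob <- function(lm, words) {
  if (length(words) == 1L && grepl("\\s", words)) {
    words <- strsplit(trimws(words), "\\s+")[[1]]
  }
  words <- tolower(as.character(words))
  words[!(words %in% lm$vocab)] <- TOK_UNK
  toks <- c(TOK_BOS, words, TOK_EOS)
  total <- 0
  for (i in 2:length(toks)) {
    start <- max(1, i - lm$order + 1)
    ctx <- if (start > i - 1) character(0) else toks[start:(i - 1)]
    total <- total + ngram_logprob(lm, ctx, toks[i])
  }
  total
}

# Sum over the full event set of P(w | context); should be 1 for any trained
# model. Used by the normalization tests.
lm_context_prob_sum <- function(lm, context) {
  events <- c(lm$vocab, TOK_EOS, TOK_UNK)
  sum(exp(ngram_logprob_batch(lm, rep(list(context), length(events)), events)))
}

#' Write a language model in ARPA format
#'
#' @param lm an `ngram_lm`.
#' @param path output file; omit to return the text lines.
#' @return the text lines, invisibly if written to a file.
#' @export
write_arpa <- function(lm, path = NULL) {
  lines <- c("\\data\\")
  for (k in seq_len(lm$order)) {
    lines <- c(lines, sprintf("ngram %d=%d", k, nrow(lm$tables[[k]])))
  }
  for (k in seq_len(lm$order)) {
    lines <- c(lines, "", sprintf("\\%d-grams:", k))
    tab <- lm$tables[[k]]
    l10 <- tab$logp / log(10)
    b10 <- tab$bow / log(10)
    has_bow <- k < lm$order
    lines <- c(lines, vapply(seq_len(nrow(tab)), function(i) {
      if (has_bow) sprintf("%.7f\t%s\t%.7f", l10[i], tab$ngram[i], b10[i])
      else sprintf("%.7f\t%s", l10[i], tab$ngram[i])
    }, ""))
  }
  lines <- c(lines, "", "\\end\\")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read an ARPA-format language model
#'
#' @param source path to an ARPA file, or a character vector of lines.
#' @return an `ngram_lm` (smoothing tagged `"backoff"`: whatever scheme
#'   produced the file, queries use standard backoff semantics).
#' @export
read_arpa <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else as.character(source)
  lines <- trimws(lines)
  i_data <- which(lines == "\\data\\")
  if (length(i_data) != 1) stop_config("ARPA parse error: missing \\data\\")
  declared <- integer(0)
  i <- i_data + 1L
  while (i <= length(lines) && grepl("^ngram ", lines[i])) {
    m <- regmatches(lines[i], regexec("^ngram ([0-9]+)=([0-9]+)$", lines[i]))[[1]]
    if (length(m) != 3) stop_config("ARPA parse error: bad count line '%s'",
                                    lines[i])
    declared[as.integer(m[2])] <- as.integer(m[3])
    i <- i + 1L
  }
  order <- length(declared)
  if (order < 1) stop_config("ARPA parse error: no ngram count lines")
  tables <- vector("list", order)
  for (k in seq_len(order)) {
    hdr <- sprintf("\\%d-grams:", k)
    i_h <- which(lines == hdr)
    if (length(i_h) != 1) stop_config("ARPA parse error: missing %s", hdr)
    rows <- list()
    j <- i_h + 1L
    while (j <= length(lines) && lines[j] != "" &&
           !startsWith(lines[j], "\\")) {
      f <- strsplit(lines[j], "[\t ]+")[[1]]
      if (length(f) < k + 1) stop_config("ARPA parse error at line %d", j)
      has_bow <- length(f) == k + 2
      rows[[length(rows) + 1L]] <- list(
        logp = as.numeric(f[1]) * log(10),
        ngram = paste(f[2:(k + 1)], collapse = " "),
        bow = if (has_bow) as.numeric(f[k + 2]) * log(10) else 0
      )
      j <- j + 1L
    }
    if (length(rows) != declared[k]) {
      stop_config("ARPA parse error: \\data\\ declares %d %d-grams, body has %d",
                  declared[k], k, length(rows))
    }
    tables[[k]] <- data.frame(
      ngram = vapply(rows, `[[`, "", "ngram"),
      logp = vapply(rows, `[[`, 0, "logp"),
      bow = vapply(rows, `[[`, 0, "bow"),
      stringsAsFactors = FALSE
    )
  }
  if (!any(lines == "\\end\\")) stop_config("ARPA parse error: missing \\end\\")
  uni <- tables[[1]]$ngram
  vocab <- sort(setdiff(uni, c(TOK_BOS, TOK_EOS, TOK_UNK)))
  lm <- structure(list(order = order, smoothing = "backoff", vocab = vocab,
                       tables = tables), class = "ngram_lm")
  lm_rebuild_env(lm)
}

#' @export
print.ngram_lm <- function(x, ...) {
  cat(sprintf("<ngram_lm> order %d (%s), %d-word vocabulary; %s n-grams\n",
              x$order, x$smoothing, length(x$vocab),
              paste(vapply(x$tables, nrow, 0L), collapse = "/")))
  invisible(x)
}
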