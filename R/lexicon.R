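#' Read a pronunciation lexicon (CMUdict text dialect)
#'
#' Parses lines of the form `WORD PH1 PH2 ...`. Variant pronunciations are
#' marked `WORD(2)`, `WORD(3)`, ...; comment lines starting with `;;;` are
#' skipped; stress digits on vowels (`AH0` -> `AH`) are stripped; words are
#' case-folded to lowercase.
#'
#' @param source path to a lexicon file, or a character vector of lines.
#' @param inventory a [phoneme_inventory()]; every parsed phoneme must
#'   belong to it.
#' @return object of class `lexicon`: a named list mapping each word to a
#'   list of pronunciations (character vectors of phoneme labels).
#' @export
read_lexicon <- function(source, inventory = phoneme_inventory()) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else as.character(source)
  entries <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, ";;;")) next
    toks <- strsplit(line, "\\s+")[[1]]
    if (length(toks) < 2) {
      stop_config("lexicon line %d: word without pronunciation", ln)
    }
    word <- tolower(sub("\\([0-9]+\\)$", "", toks[1]))
    phones <- toupper(sub("[0-9]$", "", toks[-1]))
    bad <- setdiff(phones, inventory$symbols)
    if (length(bad)) {
      stop_config("lexicon line %d: unknown phoneme label(s) %s",
                  ln, paste(bad, collapse = ", "))
    }
    entries[[word]] <- c(entries[[word]], list(phones))
  }
  if (length(entries) == 0) stop_config("empty lexicon")
  structure(entries, class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d words, %d pronunciations\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

# First (or all) pronunciations of a word, with an explicit OOV error.
lexicon_pron <- function(lexicon, word, all = FALSE) {
  word <- tolower(word)
  p <- lexicon[[word]]
  if (is.null(p)) stop_config("word not in lexicon (OOV): '%s'", word)
  if (all) p else p[[1]]
}

#' Write a lexicon in CMUdict dialect
#' @param lexicon a `lexicon`.
#' @param path output file.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- unlist(lapply(names(lexicon), function(w) {
    prons <- lexicon[[w]]
    vapply(seq_along(prons), function(i) {
      tag <- if (i == 1) toupper(w) else sprintf("%s(%d)", toupper(w), i)
      paste(tag, paste(prons[[i]], collapse = " "))
    }, "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Vocabulary of a lexicon
#'
#' @param lexicon a `lexicon`, or a character vector of words.
#' @return object of class `vocabulary`: sorted unique lowercase words.
#' @export
vocabulary <- function(lexicon) {
  words <- if (inherits(lexicon, "lexicon")) names(lexicon)
           else tolower(as.character(lexicon))
  structure(sort(unique(words)), class = "vocabulary")
}

#' The packaged 50-word lexicon
#'
#' A small communication vocabulary of 50 common English words with CMUdict
#' pronunciations, shipped with the package; the small-vocabulary regime of
#' the copy-task studies.
#'
#' @return a `lexicon`.
#' @export
lexicon_50 <- function() {
  read_lexicon(system.file("extdata", "lexicon50.txt", package = "neurotext",
                           mustWork = TRUE))
}

#' Synthetic large vocabulary
#'
#' Builds a configurable-size vocabulary of synthetic CV-patterned words with
#' rule-based pronunciations, standing in for a large open vocabulary at desk
#' scale. Words and pronunciations are deterministic in the seed.
#'
#' @param n number of words.
#' @param seed integer seed.
#' @return a `lexicon` of `n` synthetic words.
#' @export
synthetic_lexicon <- function(n = 5000L, seed = 1L) {
  onsets <- c(b = "B", d = "D", f = "F", g = "G", k = "K", l = "L", m = "M",
              n = "N", p = "P", r = "R", s = "S", t = "T", v = "V", w = "W",
              z = "Z", sh = "SH", ch = "CH", th = "TH")
  nuclei <- c(a = "AE", e = "EH", i = "IH", o = "AA", u = "AH", ee = "IY",
              oo = "UW", ai = "EY", oa = "OW")
  coda_spell <- c("", "b", "d", "g", "k", "l", "m", "n", "p", "s", "t",
                  "z", "ng")
  coda_pron <- c("", "B", "D", "G", "K", "L", "M", "N", "P", "S", "T",
                 "Z", "NG")
  with_seed(seed, {
    words <- character(0)
    prons <- list()
    seen <- new.env(parent = emptyenv())
    while (length(words) < n) {
      n_syll <- sample(1:3, 1, prob = c(0.45, 0.4, 0.15))
      spell <- ""
      pron <- character(0)
      for (s in seq_len(n_syll)) {
        o <- sample(length(onsets), 1)
        v <- sample(length(nuclei), 1)
        k <- sample(length(coda_spell), 1)
        spell <- paste0(spell, names(onsets)[o], names(nuclei)[v],
                        coda_spell[k])
        pron <- c(pron, onsets[[o]], nuclei[[v]],
                  if (coda_pron[k] != "") coda_pron[k])
      }
      if (is.null(seen[[spell]])) {
        seen[[spell]] <- TRUE
        words <- c(words, spell)
        prons[[length(words)]] <- list(pron)
      }
    }
    names(prons) <- words
    structure(prons[order(words)], class = "lexicon")
  })
}
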