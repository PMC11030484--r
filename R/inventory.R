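# The 39-phoneme ARPAbet alphabet (stress-free) plus an explicit silence token.
ARPABET_39 <- c(
  "AA", "AE", "AH", "AO", "AW", "AY", "B", "CH", "D", "DH", "EH", "ER",
  "EY", "F", "G", "HH", "IH", "IY", "JH", "K", "L", "M", "N", "NG", "OW",
  "OY", "P", "R", "S", "SH", "T", "TH", "UH", "UW", "V", "W", "Y", "Z", "ZH"
)

SIL <- "SIL"

#' Phoneme inventory
#'
#' The alphabet the decoder predicts over: the 39 stress-free ARPAbet phonemes
#' plus a silence token `"SIL"` used for non-speech frames and word
#' boundaries.
#'
#' @param extra optional extra symbols appended after the standard set.
#' @return an object of class `phoneme_inventory` with fields `symbols`
#'   (ordered labels, `SIL` last by default) and `index_of` (named integer
#'   vector of 0-based indices, contiguous from 0).
#' @export
phoneme_inventory <- function(extra = character()) {
  symbols <- c(ARPABET_39, extra, SIL)
  if (anyDuplicated(symbols)) stop_config("phoneme labels must be unique")
  idx <- seq_along(symbols) - 1L
  names(idx) <- symbols
  structure(list(symbols = symbols, index_of = idx),
            class = "phoneme_inventory")
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> ", length(x$symbols), " symbols: ",
      paste(utils::head(x$symbols, 6), collapse = " "), " ... ",
      x$symbols[length(x$symbols)], "\n", sep = "")
  invisible(x)
}

n_phonemes <- function(inventory) length(inventory$symbols)

# 1-based positions for internal matrix indexing
phoneme_id <- function(inventory, labels) {
  id <- match(labels, inventory$symbols)
  if (anyNA(id)) {
    stop_config("unknown phoneme label(s): %s",
                paste(unique(labels[is.na(id)]), collapse = ", "))
  }
  id
}

sil_id <- function(inventory) match(SIL, inventory$symbols)

#' Articulatory feature table
#'
#' Manner, place and voicing for the 39 ARPAbet phonemes. Vowels are grouped
#' by height as "manner" and frontness as "place"; diphthongs are classed by
#' their starting position. Used to test whether decoding substitutions fall
#' preferentially between similarly articulated phonemes.
#'
#' @return data.frame with columns `phoneme`, `manner`, `place`, `voiced`.
#' @export
articulatory_features <- function() {
  tab <- rbind(
    c("AA", "vowel-low",  "back",     TRUE),
    c("AE", "vowel-low",  "front",    TRUE),
    c("AH", "vowel-mid",  "central",  TRUE),
    c("AO", "vowel-mid",  "back",     TRUE),
    c("AW", "vowel-low",  "back",     TRUE),
    c("AY", "vowel-low",  "front",    TRUE),
    c("EH", "vowel-mid",  "front",    TRUE),
    c("ER", "vowel-mid",  "central",  TRUE),
    c("EY", "vowel-mid",  "front",    TRUE),
    c("IH", "vowel-high", "front",    TRUE),
    c("IY", "vowel-high", "front",    TRUE),
    c("OW", "vowel-mid",  "back",     TRUE),
    c("OY", "vowel-mid",  "back",     TRUE),
    c("UH", "vowel-high", "back",     TRUE),
    c("UW", "vowel-high", "back",     TRUE),
    c("B",  "stop",       "bilabial", TRUE),
    c("P",  "stop",       "bilabial", FALSE),
    c("D",  "stop",       "alveolar", TRUE),
    c("T",  "stop",       "alveolar", FALSE),
    c("G",  "stop",       "velar",    TRUE),
    c("K",  "stop",       "velar",    FALSE),
    c("CH", "affricate",  "postalveolar", FALSE),
    c("JH", "affricate",  "postalveolar", TRUE),
    c("F",  "fricative",  "labiodental", FALSE),
    c("V",  "fricative",  "labiodental", TRUE),
    c("TH", "fricative",  "dental",   FALSE),
    c("DH", "fricative",  "dental",   TRUE),
    c("S",  "fricative",  "alveolar", FALSE),
    c("Z",  "fricative",  "alveolar", TRUE),
    c("SH", "fricative",  "postalveolar", FALSE),
    c("ZH", "fricative",  "postalveolar", TRUE),
    c("HH", "fricative",  "glottal",  FALSE),
    c("M",  "nasal",      "bilabial", TRUE),
    c("N",  "nasal",      "alveolar", TRUE),
    c("NG", "nasal",      "velar",    TRUE),
    c("L",  "approximant","alveolar", TRUE),
    c("R",  "approximant","alveolar", TRUE),
    c("W",  "approximant","bilabial", TRUE),
    c("Y",  "approximant","palatal",  TRUE)
  )
  data.frame(phoneme = tab[, 1], manner = tab[, 2], place = tab[, 3],
             voiced = as.logical(tab[, 4]), stringsAsFactors = FALSE)
}
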