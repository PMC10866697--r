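#' Assemble the word feature space for a lexicon
#'
#' Builds, once, everything the encoding and decoding stages need to embed
#' words: the three phoneme inventories, the syllable-template inventory of
#' the lexicon, and per-family design matrices (one row per word).
#'
#' Families and their regressors:
#' \describe{
#'   \item{place}{10 count columns (8 consonant places + 2 vowel heights)}
#'   \item{manner}{6 consonant-manner count columns (vowels carry no manner;
#'     set `manner_vowels = TRUE` to append the two height columns)}
#'   \item{cardinal}{8 cardinal-vowel count columns}
#'   \item{syllable}{binary indicator per inventory template (default top 10)}
#'   \item{morpheme}{`has_prefix`, `has_suffix` indicators; `n_phonemes` is
#'     carried separately as the word-length covariate}
#' }
#'
#' @param words List of `word_form`s or a `lexicon_table()` tibble.
#' @param top_k Syllable-inventory size.
#' @param manner_vowels Include vowel-height columns in the manner family.
#' @param syll_inv Optionally reuse an existing syllable inventory (e.g. the
#'   one the ground truth was generated against).
#' @return Object of class `feature_space`: inventories plus `design`, a
#'   named list of numeric matrices, and `n_phonemes`.
#' @export
feature_space <- function(words, top_k = 10, manner_vowels = FALSE,
                          syll_inv = NULL) {
  if (is.data.frame(words)) words <- table_to_words(words)
  place_inv <- phoneme_inventory("place")
  manner_inv <- phoneme_inventory("manner")
  cardinal_inv <- phoneme_inventory("cardinal_vowel")
  syll_inv <- syll_inv %||% syllable_inventory(words, top_k = top_k,
                                               place_inv = place_inv)

  stack <- function(inv) {
    t(vapply(words, function(w) phoneme_vector(w, inv)$values,
             numeric(length(inv$groups))))
  }
  place <- stack(place_inv)
  manner <- stack(manner_inv)
  if (manner_vowels) {
    manner <- cbind(manner, place[, c("high", "mid_low"), drop = FALSE])
  }
  cardinal <- stack(cardinal_inv)
  syllable <- t(vapply(words, function(w) {
    syllable_vector(w, syll_inv, place_inv)$values
  }, numeric(length(syll_inv$templates))))
  morpheme <- cbind(
    has_prefix = as.numeric(vapply(words, `[[`, logical(1), "has_prefix")),
    has_suffix = as.numeric(vapply(words, `[[`, logical(1), "has_suffix"))
  )

  structure(
    list(
      place_inv = place_inv, manner_inv = manner_inv,
      cardinal_inv = cardinal_inv, syll_inv = syll_inv,
      design = list(place = place, manner = manner, cardinal = cardinal,
                    syllable = syllable, morpheme = morpheme),
      n_phonemes = vapply(words, `[[`, integer(1), "n_phonemes"),
      words = words
    ),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat("<feature_space>", length(x$words), "words; families:",
      paste(sprintf("%s(%d)", names(x$design),
                    vapply(x$design, ncol, integer(1))), collapse = ", "),
      "\n")
  invisible(x)
}

feature_families <- function(fs) names(fs$design)
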