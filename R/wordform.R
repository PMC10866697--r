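#' Parse a word into a validated word form
#'
#' A word form couples a word's orthography with its phoneme sequence
#' (ARPAbet symbols), a syllabification (contiguous index spans that
#' partition the phoneme sequence) and bound-morphology flags. Word forms
#' are the unit that every feature-space embedding consumes.
#'
#' @param orthography Word as text.
#' @param phonemes Character vector of phoneme symbols, in order.
#' @param syllables List of integer vectors, each the (1-based, contiguous)
#'   phoneme indices of one syllable; together they must partition the
#'   phoneme sequence. Defaults to a single syllable spanning the word.
#' @param has_prefix,has_suffix Bound-morpheme flags (e.g. 're-', '-ed').
#'
#' @return An object of class `word_form`.
#' @export
#' @examples
#' parse_word("like", c("L", "AY", "K"))
#' parse_word("directed", c("D", "ER", "EH", "K", "T", "IH", "D"),
#'            syllables = list(1:2, 3:7), has_suffix = TRUE)
parse_word <- function(orthography, phonemes, syllables = NULL,
                       has_prefix = FALSE, has_suffix = FALSE) {
  if (length(phonemes) == 0) {
    abort("empty phoneme sequence", class = "phonopop_empty_pronunciation")
  }
  n <- length(phonemes)
  if (is.null(syllables)) syllables <- list(seq_len(n))
  syllables <- lapply(syllables, as.integer)

  flat <- unlist(syllables)
  contiguous <- all(vapply(syllables, function(s) {
    length(s) > 0 && all(diff(s) == 1L)
  }, logical(1)))
  if (!contiguous || !identical(sort(flat), seq_len(n)) ||
      anyDuplicated(flat) > 0) {
    abort("syllable spans must be contiguous, non-overlapping and cover all phonemes",
          class = "phonopop_bad_syllabification")
  }
  # spans must appear in word order
  starts <- vapply(syllables, function(s) s[1], integer(1))
  syllables <- syllables[order(starts)]

  structure(
    list(
      orthography = as.character(orthography),
      phonemes = as.character(phonemes),
      syllables = syllables,
      has_prefix = isTRUE(has_prefix),
      has_suffix = isTRUE(has_suffix),
      n_phonemes = n
    ),
    class = "word_form"
  )
}

#' @export
print.word_form <- function(x, ...) {
  syl <- vapply(x$syllables, function(s) paste(x$phonemes[s], collapse = "-"),
                character(1))
  cat("<word_form>", x$orthography, ":", paste(syl, collapse = " | "))
  if (x$has_prefix) cat(" [prefix]")
  if (x$has_suffix) cat(" [suffix]")
  cat("\n")
  invisible(x)
}

#' Count-vector embedding of a word in a phoneme inventory
#'
#' Embed a word in the articulatory group space of `inv`: entry *j* counts
#' how many of the word's phonemes fall in group *j*. Under the canonical
#' place ordering, 'like' (L-AY-K) gives `c(0,0,0,1,0,0,1,0,0,1)`.
#' Phonemes outside the grouping's domain (vowels under `"manner"`,
#' consonants under `"cardinal_vowel"`) are ignored.
#'
#' @param word A `word_form`.
#' @param inv A `phoneme_inventory`.
#' @return A `feature_vector`: list with integer `values` (named by group)
#'   and the `grouping` tag.
#' @export
#' @examples
#' inv <- phoneme_inventory("place")
#' phoneme_vector(parse_word("like", c("L", "AY", "K")), inv)$values
phoneme_vector <- function(word, inv) {
  stopifnot(inherits(word, "word_form"), inherits(inv, "phoneme_inventory"))
  grp <- map_symbols(word$phonemes, inv)
  counts <- vapply(inv$groups, function(g) sum(grp == g, na.rm = TRUE),
                   integer(1))
  structure(list(values = counts, grouping = inv$grouping),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>", x$grouping, ": [",
      paste(x$values, collapse = " "), "]\n")
  invisible(x)
}

#' Bound-morphology features of a word
#'
#' Returns the two bound-morpheme indicators together with the phoneme
#' count, which morphology models carry as a word-length covariate.
#'
#' @param word A `word_form`.
#' @return Named list with `has_prefix`, `has_suffix`, `n_phonemes`.
#' @export
morpheme_features <- function(word) {
  stopifnot(inherits(word, "word_form"))
  list(has_prefix = word$has_prefix, has_suffix = word$has_suffix,
       n_phonemes = word$n_phonemes)
}

# Place-group label sequence of one syllable span (vowels use height labels).
syllable_template <- function(word, span, place_inv) {
  paste(map_symbols(word$phonemes[span], place_inv), collapse = "-")
}

word_templates <- function(word, place_inv) {
  vapply(word$syllables, function(s) syllable_template(word, s, place_inv),
         character(1))
}

#' Tabulate a lexicon of word forms
#'
#' Convenience conversion from a list of `word_form`s to a tibble with one
#' row per word; feature-space embeddings can then be appended columnwise.
#'
#' @param words List of `word_form`s.
#' @return Tibble with columns `orthography`, `phonemes` (list), `syllables`
#'   (list), `has_prefix`, `has_suffix`, `n_phonemes`.
#' @export
lexicon_table <- function(words) {
  tibble(
    orthography = vapply(words, `[[`, character(1), "orthography"),
    phonemes = lapply(words, `[[`, "phonemes"),
    syllables = lapply(words, `[[`, "syllables"),
    has_prefix = vapply(words, `[[`, logical(1), "has_prefix"),
    has_suffix = vapply(words, `[[`, logical(1), "has_suffix"),
    n_phonemes = vapply(words, `[[`, integer(1), "n_phonemes")
  )
}

# Reconstruct word_form objects from a lexicon table row range.
table_to_words <- function(tbl) {
  lapply(seq_len(nrow(tbl)), function(i) {
    parse_word(tbl$orthography[i], tbl$phonemes[[i]], tbl$syllables[[i]],
               tbl$has_prefix[i], tbl$has_suffix[i])
  })
}
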