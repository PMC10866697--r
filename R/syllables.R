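#' Most common syllable templates of a lexicon
#'
#' A syllable template is the ordered sequence of place groups of one
#' syllable (e.g. 'back' contains the single template
#' bilabial-mid_low-velar). The inventory keeps the `top_k` most frequent
#' templates across the lexicon; ties at the cut are broken
#' lexicographically on the template string so the inventory is
#' deterministic. Lone vowels count as syllables only when a span consists
#' of a single unbound vowel (they always form their own template here
#' because spans partition the word).
#'
#' @param words List of `word_form`s (or a `lexicon_table()` tibble).
#' @param top_k Number of templates to keep (default 10).
#' @param place_inv Place inventory used to label the templates.
#' @return An object of class `syllable_inventory` with `templates`
#'   (character, ordered by frequency then template string) and `freq`.
#' @export
syllable_inventory <- function(words, top_k = 10,
                               place_inv = phoneme_inventory("place")) {
  if (is.data.frame(words)) words <- table_to_words(words)
  assert_that(length(words) > 0, "lexicon is empty")
  assert_that(top_k >= 1, "top_k must be >= 1")

  templ <- unlist(lapply(words, word_templates, place_inv = place_inv))
  tab <- sort(table(templ), decreasing = TRUE)
  # deterministic: frequency desc, then lexicographic on template
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  tab <- tab[ord]
  if (length(tab) < top_k) {
    warn(sprintf("only %d distinct syllable templates (top_k = %d); keeping all",
                 length(tab), top_k))
    top_k <- length(tab)
  }
  keep <- head(tab, top_k)
  structure(
    list(templates = names(keep), freq = as.integer(keep)),
    class = "syllable_inventory"
  )
}

#' @export
print.syllable_inventory <- function(x, ...) {
  cat("<syllable_inventory>", length(x$templates), "templates\n")
  print(tibble(template = x$templates, freq = x$freq), n = length(x$templates))
  invisible(x)
}

#' Binary syllable-indicator vector of a word
#'
#' One indicator per inventory template; a template is present only when
#' some syllable span of the word has exactly that place-group sequence.
#' Unlike the phoneme count vector, this embedding is order-sensitive:
#' 'god' (G-AA-D, velar-mid_low-alveolar) and 'dog' (D-AO-G,
#' alveolar-mid_low-velar) share a phoneme vector but match different
#' templates.
#'
#' @param word A `word_form`.
#' @param inv A `syllable_inventory`.
#' @param place_inv Place inventory used to label the word's syllables.
#' @return A `feature_vector` with binary `values` named by template.
#' @export
syllable_vector <- function(word, inv, place_inv = phoneme_inventory("place")) {
  stopifnot(inherits(word, "word_form"), inherits(inv, "syllable_inventory"))
  present <- word_templates(word, place_inv)
  vals <- as.integer(inv$templates %in% present)
  names(vals) <- inv$templates
  structure(list(values = vals, grouping = "syllable"),
            class = "feature_vector")
}

#' Classify a word against a target syllable template
#'
#' Places a word into exactly one of five mutually exclusive control
#' categories relative to a target syllable, evaluated in priority order:
#' \describe{
#'   \item{contains_syllable}{the target sequence occurs inside a single
#'     syllable span (exact template matches included)}
#'   \item{same_phonemes_diff_order}{a syllable has the same place-group
#'     multiset as the target but in a different order (e.g. G-AA-D for
#'     'god' against the target D-AH-G)}
#'   \item{same_phonemes_diff_segmentation}{the target sequence occurs in
#'     the word's place-group string but straddles a syllable boundary}
#'   \item{phonemes_without_syllable}{the word shares at least one place
#'     group with the target but none of the above hold}
#'   \item{different_phonemes}{no place group in common}
#' }
#'
#' @param word A `word_form`.
#' @param target_template Target as a place-group sequence string
#'   (e.g. `"alveolar-mid_low-velar"`) or character vector of groups.
#' @param place_inv Place inventory.
#' @return Single character category.
#' @export
classify_syllable_control <- function(word, target_template,
                                      place_inv = phoneme_inventory("place")) {
  stopifnot(inherits(word, "word_form"))
  tgt <- if (length(target_template) == 1) {
    strsplit(target_template, "-", fixed = TRUE)[[1]]
  } else {
    as.character(target_template)
  }
  assert_that(length(tgt) >= 1, "target template is empty")

  spans <- lapply(word$syllables, function(s) map_symbols(word$phonemes[s], place_inv))
  word_groups <- map_symbols(word$phonemes, place_inv)

  contains_run <- function(g, tgt) {
    n <- length(g); k <- length(tgt)
    n >= k && any(vapply(seq_len(n - k + 1), function(i) {
      identical(g[i:(i + k - 1)], tgt)
    }, logical(1)))
  }

  # target sequence inside a single syllable (exact template match included)
  if (any(vapply(spans, contains_run, logical(1), tgt = tgt))) {
    return("contains_syllable")
  }

  same_multiset <- any(vapply(spans, function(g) {
    length(g) == length(tgt) && identical(sort(g), sort(tgt))
  }, logical(1)))
  if (same_multiset) return("same_phonemes_diff_order")

  # target occurs as a contiguous run in the whole word but across a boundary
  if (contains_run(word_groups, tgt)) return("same_phonemes_diff_segmentation")

  if (any(tgt %in% word_groups)) return("phonemes_without_syllable")
  "different_phonemes"
}
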