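#' Articulatory phoneme inventories
#'
#' Build one of the three phoneme grouping schemes used throughout the
#' package. Consonants are grouped either by place of articulation
#' (bilabial, labiodental, dental, alveolar, postalveolar, palatal, velar,
#' glottal) or by manner of articulation (stop, fricative, affricate, nasal,
#' liquid, glide); vowels are grouped by relative tongue height (high vs
#' mid-low) or assigned to one of eight primary cardinal vowel classes.
#'
#' The `"place"` grouping is the ten-dimensional space used for the main
#' word embeddings: the eight consonant places ordered front (lips) to back
#' (glottis), followed by the two vowel-height classes. Group order is fixed
#' so that feature vectors are comparable across sessions and runs; under
#' this canonical order the word 'like' (L-AY-K: alveolar, mid-low, velar)
#' maps to `c(0,0,0,1,0,0,1,0,0,1)`.
#'
#' @param grouping One of `"place"`, `"manner"`, `"cardinal_vowel"`.
#' @param symbol_table Optional data frame with columns `symbol`, `type`,
#'   `place`, `manner`, `vowel_height`, `cardinal_class` overriding the
#'   bundled General American ARPAbet table.
#'
#' @return An object of class `phoneme_inventory`: a list with `grouping`,
#'   `groups` (ordered character vector) and `symbol_map` (a tibble mapping
#'   each phoneme symbol to its group).
#' @export
#' @examples
#' inv <- phoneme_inventory("place")
#' inv$groups
phoneme_inventory <- function(grouping = c("place", "manner", "cardinal_vowel"),
                              symbol_table = NULL) {
  if (length(grouping) != 1 || !grouping %in% c("place", "manner", "cardinal_vowel")) {
    abort(
      paste0("unknown grouping: ", paste(grouping[1], collapse = ", "),
             " (must be 'place', 'manner' or 'cardinal_vowel')"),
      class = "phonopop_unknown_grouping"
    )
  }
  tab <- symbol_table %||% arpabet_table()

  groups <- switch(grouping,
    place = c(
      "bilabial", "labiodental", "dental", "alveolar", "postalveolar",
      "palatal", "velar", "glottal", "high", "mid_low"
    ),
    manner = c("stop", "fricative", "affricate", "nasal", "liquid", "glide"),
    cardinal_vowel = c("i", "e", "e_open", "a", "alpha", "o_open", "o", "u")
  )

  group_of <- switch(grouping,
    place = ifelse(tab$type == "consonant", tab$place, tab$vowel_height),
    manner = ifelse(tab$type == "consonant", tab$manner, NA_character_),
    cardinal_vowel = ifelse(tab$type == "vowel", tab$cardinal_class, NA_character_)
  )
  symbol_map <- tibble(
    symbol = tab$symbol, type = tab$type, group = group_of
  ) %>% filter(!is.na(.data$group))

  bad <- setdiff(symbol_map$group, groups)
  assert_that(length(bad) == 0,
              paste0("symbol table contains unknown groups: ",
                     paste(bad, collapse = ", ")))

  structure(
    list(grouping = grouping, groups = groups, symbol_map = symbol_map),
    class = "phoneme_inventory"
  )
}

arpabet_table <- function() {
  path <- system.file("extdata", "arpabet_groups.tsv", package = "phonopop")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA"), progress = FALSE)
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> grouping:", x$grouping,
      "|", length(x$groups), "groups\n")
  cat(paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

# Map a vector of phoneme symbols to their group labels under `inv`.
# Symbols outside the grouping's domain (e.g. vowels under "manner") map to
# NA; unknown symbols raise an error naming the offender.
map_symbols <- function(symbols, inv) {
  known <- arpabet_known_symbols(inv)
  unknown <- setdiff(symbols, known)
  if (length(unknown) > 0) {
    abort(paste0("phoneme symbol(s) not in inventory: ",
                 paste(unique(unknown), collapse = ", ")),
          class = "phonopop_unknown_symbol")
  }
  inv$symbol_map$group[match(symbols, inv$symbol_map$symbol)]
}

arpabet_known_symbols <- function(inv) {
  # the full symbol universe, not just those mapped by this grouping:
  # a vowel is "known" to the manner inventory even though it maps to NA
  union(inv$symbol_map$symbol, arpabet_table()$symbol)
}

#' Hamming distance between feature vectors
#'
#' Number of positions at which two equal-length vectors differ. Used both
#' between word count vectors (e.g. 'like' vs 'bike' differ at the alveolar
#' and bilabial positions, distance 2) and between a word's signed presence
#' vector and a neuron's preferred-composition sign vector.
#'
#' @param u,v Numeric/integer vectors of equal length.
#' @return Integer in `[0, length(u)]`.
#' @export
#' @examples
#' hamming_distance(c(0, 1, 1), c(1, 1, 0))
hamming_distance <- function(u, v) {
  u_vals <- if (inherits(u, "feature_vector")) u$values else u
  v_vals <- if (inherits(v, "feature_vector")) v$values else v
  if (inherits(u, "feature_vector") && inherits(v, "feature_vector") &&
      !identical(u$grouping, v$grouping)) {
    abort("feature vectors come from different groupings",
          class = "phonopop_length_mismatch")
  }
  if (length(u_vals) != length(v_vals)) {
    abort("vectors must have equal length", class = "phonopop_length_mismatch")
  }
  sum(u_vals != v_vals)
}
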