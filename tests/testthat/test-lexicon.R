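test_that("inventories have the documented groups and sizes", {
  place <- phoneme_inventory("place")
  expect_length(place$groups, 10)
  expect_identical(place$groups[1:8],
                   c("bilabial", "labiodental", "dental", "alveolar",
                     "postalveolar", "palatal", "velar", "glottal"))
  expect_identical(place$groups[9:10], c("high", "mid_low"))

  manner <- phoneme_inventory("manner")
  expect_setequal(manner$groups,
                  c("stop", "fricative", "affricate", "nasal", "liquid",
                    "glide"))
  expect_length(phoneme_inventory("cardinal_vowel")$groups, 8)
  expect_error(phoneme_inventory("prosody"),
               class = "phonopop_unknown_grouping")
})

test_that("every consonant has one place and one manner; vowels one height and one cardinal class", {
  place <- phoneme_inventory("place")
  manner <- phoneme_inventory("manner")
  cardinal <- phoneme_inventory("cardinal_vowel")
  cons <- place$symbol_map$symbol[place$symbol_map$type == "consonant"]
  vows <- place$symbol_map$symbol[place$symbol_map$type == "vowel"]
  expect_setequal(cons, manner$symbol_map$symbol)
  expect_setequal(vows, cardinal$symbol_map$symbol)
  expect_false(anyDuplicated(place$symbol_map$symbol) > 0)
})

test_that("word parsing validates pronunciation and syllable spans", {
  w <- parse_word("like", c("L", "AY", "K"))
  expect_s3_class(w, "word_form")
  expect_identical(w$n_phonemes, 3L)
  expect_length(w$syllables, 1)

  expect_error(parse_word("x", character(0)),
               class = "phonopop_empty_pronunciation")
  expect_error(parse_word("like", c("L", "AY", "K"), list(1:2)),
               class = "phonopop_bad_syllabification")
  expect_error(parse_word("like", c("L", "AY", "K"), list(1:2, 2:3)),
               class = "phonopop_bad_syllabification")
})

test_that("phoneme vectors reproduce the canonical embeddings", {
  inv <- place_inv()
  expect_equal(unname(phoneme_vector(w_like(), inv)$values),
               c(0, 0, 0, 1, 0, 0, 1, 0, 0, 1))
  expect_equal(unname(phoneme_vector(w_bike(), inv)$values),
               c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1))
  kick <- parse_word("kick", c("K", "IH", "K"))
  v <- phoneme_vector(kick, inv)$values
  expect_equal(unname(v[c("velar", "high")]), c(2, 1))
  expect_equal(sum(v), 3)

  # 'back' is a bilabial - mid_low - velar sequence
  back <- parse_word("back", c("B", "AE", "K"))
  expect_identical(
    unname(vapply(back$phonemes, function(s) {
      inv$symbol_map$group[inv$symbol_map$symbol == s]
    }, character(1))),
    c("bilabial", "mid_low", "velar")
  )

  expect_error(phoneme_vector(parse_word("x", c("QQ")), inv),
               class = "phonopop_unknown_symbol")
})

test_that("phoneme vectors are permutation invariant and sum to n_phonemes", {
  inv <- place_inv()
  lex <- generate_lexicon(30, seed = 5)
  for (w in lex) {
    v <- phoneme_vector(w, inv)$values
    expect_equal(sum(v), w$n_phonemes)
    perm <- parse_word(w$orthography, sample(w$phonemes))
    expect_equal(phoneme_vector(perm, inv)$values, v)
  }
})

test_that("hamming distance matches examples and satisfies metric axioms", {
  inv <- place_inv()
  u <- phoneme_vector(w_like(), inv)
  v <- phoneme_vector(w_bike(), inv)
  expect_identical(hamming_distance(u, u), 0L)
  expect_identical(hamming_distance(u, v), 2L)
  expect_identical(hamming_distance(rep(0, 10), rep(1, 10)), 10L)
  expect_error(hamming_distance(1:3, 1:4), class = "phonopop_length_mismatch")

  withr::with_seed(99, {
    for (i in 1:50) {
      a <- rpois(10, 1); b <- rpois(10, 1); cc <- rpois(10, 1)
      expect_identical(hamming_distance(a, b), hamming_distance(b, a))
      expect_true(hamming_distance(a, cc) <=
                    hamming_distance(a, b) + hamming_distance(b, cc))
      expect_identical(hamming_distance(a, a), 0L)
    }
  })
})

test_that("syllable inventory keeps the top-k templates deterministically", {
  lex <- generate_lexicon(400, seed = 11)
  inv <- syllable_inventory(lex, top_k = 10)
  expect_length(inv$templates, 10)
  expect_true(all(diff(inv$freq) <= 0))

  # exhaustion: fewer distinct templates than requested
  tiny <- list(w_god(), w_dog(), parse_word("dig", c("D", "IH", "G")))
  expect_warning(inv3 <- syllable_inventory(tiny, top_k = 10),
                 "keeping all")
  expect_length(inv3$templates, 3)

  # tie at the cut resolved lexicographically on the template string
  lex_tie <- list(w_god(), w_god(), w_dog(), w_dog(),
                  parse_word("pa", c("P", "AA")))
  inv_tie <- syllable_inventory(lex_tie, top_k = 1)
  tmpl_god <- "velar-mid_low-alveolar"
  tmpl_dog <- "alveolar-mid_low-velar"
  expect_identical(inv_tie$templates, min(tmpl_god, tmpl_dog))
})

test_that("syllable vectors are order-sensitive where phoneme vectors are not", {
  inv <- place_inv()
  lex <- list(w_god(), w_dog())
  syl_inv <- syllable_inventory(lex, top_k = 10) |> suppressWarnings()
  vg <- syllable_vector(w_god(), syl_inv)
  vd <- syllable_vector(w_dog(), syl_inv)
  expect_equal(phoneme_vector(w_god(), inv)$values,
               phoneme_vector(w_dog(), inv)$values)
  expect_false(identical(vg$values, vd$values))
  expect_true(all(vg$values %in% c(0L, 1L)))

  # a word containing no inventory template maps to the zero vector
  far <- parse_word("she", c("SH", "IY"))
  expect_equal(sum(syllable_vector(far, syl_inv)$values), 0)
})

test_that("syllable-control classification follows the documented priority", {
  tmpl_dog <- "alveolar-mid_low-velar"
  expect_identical(classify_syllable_control(w_dog(), tmpl_dog),
                   "contains_syllable")
  expect_identical(classify_syllable_control(w_god(), tmpl_dog),
                   "same_phonemes_diff_order")
  # same groups, contiguous in the word but split across syllables
  split_word <- parse_word("dahgi", c("D", "AA", "G", "IY"),
                           syllables = list(1:2, 3:4))
  expect_identical(classify_syllable_control(split_word, tmpl_dog),
                   "same_phonemes_diff_segmentation")
  some <- parse_word("dip", c("D", "IH", "P"))
  expect_identical(classify_syllable_control(some, tmpl_dog),
                   "phonemes_without_syllable")
  none <- parse_word("fee", c("F", "IY"))
  expect_identical(classify_syllable_control(none, tmpl_dog),
                   "different_phonemes")
  # target inside a longer single syllable still counts as contained
  long_syll <- parse_word("dogz", c("D", "AA", "G", "Z"),
                          syllables = list(1:4))
  expect_identical(classify_syllable_control(long_syll, tmpl_dog),
                   "contains_syllable")
})

test_that("an indicator set in the syllable vector implies contains_syllable", {
  lex <- generate_lexicon(150, seed = 21)
  syl_inv <- syllable_inventory(lex, top_k = 10)
  for (w in lex[1:60]) {
    v <- syllable_vector(w, syl_inv)$values
    for (j in which(v == 1)) {
      expect_identical(classify_syllable_control(w, syl_inv$templates[j]),
                       "contains_syllable")
    }
  }
})

test_that("morphology features carry the flags and word length", {
  directed <- parse_word("directed", c("D", "ER", "EH", "K", "T", "IH", "D"),
                         has_suffix = TRUE)
  retry <- parse_word("retry", c("R", "IY", "T", "R", "AY"),
                      has_prefix = TRUE)
  cat3 <- parse_word("cat", c("K", "AE", "T"))
  expect_true(morpheme_features(directed)$has_suffix)
  expect_true(morpheme_features(retry)$has_prefix)
  mf <- morpheme_features(cat3)
  expect_false(mf$has_prefix || mf$has_suffix)
  expect_identical(mf$n_phonemes, 3L)
})

test_that("band powers: zero input, RMS closed form, tone localization", {
  rate <- 16000
  zero <- band_powers_from_waveform(rep(0, 1000), rate)
  expect_equal(zero$band_power, rep(0, 10))
  expect_equal(zero$rms, 0)

  const <- band_powers_from_waveform(rep(-0.4, 500), rate)
  expect_equal(const$rms, 0.4)

  # tone at a band centre dominates that band; checked against a direct
  # periodogram computed independently
  edges <- exp(seq(log(200), log(5000), length.out = 11))
  centre <- sqrt(edges[4] * edges[5])
  t <- seq(0, 0.2, by = 1 / rate)
  tone <- sin(2 * pi * centre * t)
  bp <- band_powers_from_waveform(tone, rate)
  expect_identical(which.max(bp$band_power), 4L)

  pg <- Mod(stats::fft(tone))^2 / length(tone)
  freq <- (seq_along(tone) - 1) * rate / length(tone)
  peak_freq <- freq[which.max(pg[freq <= rate / 2])]
  expect_lt(abs(peak_freq - centre), 10)

  expect_error(band_powers_from_waveform(c(1), rate),
               class = "phonopop_short_segment")
  expect_error(band_powers_from_waveform(rep(1, 100), 8000),
               class = "phonopop_short_segment")
})
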