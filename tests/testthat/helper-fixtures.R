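# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

place_inv <- function() memo("place_inv", phoneme_inventory("place"))

w_like <- function() parse_word("like", c("L", "AY", "K"))
w_bike <- function() parse_word("bike", c("B", "AY", "K"))
w_god  <- function() parse_word("god", c("G", "AA", "D"))
w_dog  <- function() parse_word("dog", c("D", "AA", "G"))

# small two-participant bundle used across decoding/selectivity tests
small_bundle <- function() {
  memo("small_bundle", {
    cfg <- sim_config(n_participants = 2, units_range = c(10, 14),
                      words_per_participant = 120, seed = 42)
    simulate_bundle(cfg, n_lexicon = 120)
  })
}

# single-participant bundle with strong planted place coding
coded_bundle <- function() {
  memo("coded_bundle", {
    cfg <- sim_config(
      n_participants = 1, units_range = c(30, 30),
      words_per_participant = 400,
      tuned_fractions = c(place = 0.2, syllable = 0, morpheme = 0),
      effect_size = 1, seed = 101
    )
    simulate_bundle(cfg, n_lexicon = 200)
  })
}

# direct Poisson count simulation for GLM-level tests: counts for n_neurons
# whose log-rate is beta0 + X %*% beta (X from a synthetic lexicon design)
sim_counts <- function(X, beta, beta0 = log(1.5), seed = 1) {
  withr::with_seed(seed, {
    eta <- beta0 + as.numeric(X %*% beta)
    rpois(nrow(X), exp(eta))
  })
}

# design matrix of place counts for a seeded lexicon
place_design <- function(n_words, seed = 7) {
  memo(paste0("design", n_words, "_", seed), {
    lex <- generate_lexicon(n_words, seed = seed)
    feature_space(lex)$design$place
  })
}
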