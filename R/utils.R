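# Internal helpers: seeded evaluation and seed-stream derivation.

# Evaluate `expr` under a temporary RNG state. Restores (or removes) the
# global .Random.seed afterwards so seeded helpers never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage substream seed from a master seed. Linear-congruential
# style mix, kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    lexicon = 101L, ground_truth = 211L, session = 307L, acoustics = 401L,
    pseudopop = 503L, decoder = 601L, null = 701L, temporal = 809L,
    subspace = 907L, pipeline = 1009L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else {
    sum(utf8ToInt(stage)) %% 1000L
  }
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

# sample from the elements of x (never from 1:x when x is scalar)
sample_vec <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

assert_that <- function(ok, msg, class = "phonopop_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
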