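test_that("AUC anchors, tie handling and the pair-count oracle agree", {
  expect_equal(score_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  y <- rep(c(0, 1), 8)
  expect_equal(score_auc(y, y), 1)
  expect_equal(score_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(score_auc(1:4, rep(1, 4)), class = "phonopop_one_class")

  # brute-force Mann-Whitney pair counting, ties worth one half
  auc_pairs <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(5:60, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # plenty of ties
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) next
      expect_equal(score_auc(s, l), auc_pairs(s, l))
      # invariance under strictly monotone transforms
      expect_equal(score_auc(exp(3 * s) - 2, l), score_auc(s, l))
    }
  })
})

test_that("score_auc agrees with an independent ROC implementation", {
  withr::with_seed(17, {
    s <- rnorm(200); l <- rbinom(200, 1, 0.4)
    expect_equal(score_auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("pseudopopulation matching follows the min-count rule without duplication", {
  # two participants, controlled pattern counts: 30 vs 20 for one pattern
  withr::with_seed(23, {
    mk <- function(part, n_a, n_b, units) {
      lab <- c(rep(TRUE, n_a), rep(FALSE, n_b))
      df <- tibble::tibble(
        participant = part,
        word_id = sprintf("%s_w%03d", part, seq_len(n_a + n_b)),
        label_x = lab
      )
      rates <- matrix(rnorm((n_a + n_b) * length(units)),
                      ncol = length(units),
                      dimnames = list(NULL, paste0("u_", units)))
      dplyr::bind_cols(df, tibble::as_tibble(rates))
    }
    tr <- dplyr::bind_rows(mk("p1", 30, 25, c("a1", "a2")),
                           mk("p2", 20, 40, c("b1", "b2", "b3")))
    # NA-mask foreign units as decoding_trials() does
    tr[tr$participant == "p1", c("u_b1", "u_b2", "u_b3")] <- NA
    tr[tr$participant == "p2", c("u_a1", "u_a2")] <- NA

    P <- build_pseudopopulation(tr, seed = 5)
    expect_identical(sum(P$labels[, 1]), 20L)    # min(30, 20)
    expect_identical(sum(!P$labels[, 1]), 25L)   # min(25, 40)
    expect_identical(ncol(P$rates), 5L)
    # duplication audit on (participant, word_id)
    expect_identical(anyDuplicated(P$provenance[c("participant", "word_id")]),
                     0L)
  })
})

test_that("single-session pseudopopulation is an identity pass-through", {
  s <- coded_bundle()
  tr <- decoding_trials(s, family = "place")
  P <- build_pseudopopulation(tr, seed = 2)
  expect_identical(nrow(P$rates), nrow(tr))
  expect_identical(P$provenance$word_id, tr$word_id)
})

test_that("a pattern absent in one participant is dropped and logged", {
  s <- small_bundle()
  tr <- decoding_trials(s, family = "place")
  P <- build_pseudopopulation(tr, seed = 3)
  lab_cols <- grep("^label_", names(tr), value = TRUE)
  pat <- apply(as.matrix(tr[lab_cols]) > 0, 1, paste, collapse = "")
  tab <- table(pat, tr$participant)
  absent <- rownames(tab)[apply(tab, 1, min) == 0]
  expect_setequal(P$matching_log$pattern, absent)
})

test_that("decoders separate a planted code and stay at chance on shuffled labels", {
  # linearly separable planted code
  withr::with_seed(71, {
    n <- 400; p <- 30
    y <- rbinom(n, 1, 0.5) == 1
    x <- matrix(rnorm(n * p), n, p)
    x[y, 1:5] <- x[y, 1:5] + 2
    tr <- dplyr::bind_cols(
      tibble::tibble(participant = "p1", word_id = sprintf("w%03d", 1:n),
                     label_sig = y),
      tibble::as_tibble(stats::setNames(as.data.frame(x), paste0("u_", 1:p)))
    )
    P <- build_pseudopopulation(tr, seed = 1)
    cfg <- decoder_config(n_splits = 8, cost_grid = 1, seed = 11)
    res <- train_feature_decoders(P, cfg, keep_models = FALSE)
    expect_gte(res$summary$mean_auc, 0.95)

    # labels independent of rates: mean AUC near one half
    P0 <- P
    P0$labels <- matrix(rbinom(n, 1, 0.5) == 1, ncol = 1,
                        dimnames = list(NULL, "sig"))
    res0 <- train_feature_decoders(P0, cfg, keep_models = FALSE)
    expect_gte(res0$summary$mean_auc, 0.45)
    expect_lte(res0$summary$mean_auc, 0.55)
  })
})

test_that("gamma defaults to one over the neuron count", {
  s <- coded_bundle()
  tr <- decoding_trials(s, family = "place")
  P <- build_pseudopopulation(tr, seed = 2)
  res <- train_feature_decoders(P, decoder_config(n_splits = 2, cost_grid = 1,
                                                  seed = 1),
                                keep_models = FALSE)
  expect_equal(res$gamma, 1 / ncol(P$rates))
})

test_that("per-split mean AUC averages only the trained dimensions", {
  s <- small_bundle()
  tr <- decoding_trials(s, family = "place")
  P <- build_pseudopopulation(tr, seed = 3)
  res <- train_feature_decoders(P, decoder_config(n_splits = 3, cost_grid = 1,
                                                  min_positives = 10, seed = 9),
                                keep_models = FALSE)
  expect_gt(length(res$skipped), 0)
  manual <- colMeans(res$auc[res$trainable, , drop = FALSE], na.rm = TRUE)
  expect_equal(res$split_mean, manual)
  expect_true(all(is.na(res$auc[!res$trainable, ])))
})

test_that("train/test splits are disjoint, also under model switching", {
  s <- coded_bundle()
  tr <- decoding_trials(s, family = "place")
  P <- build_pseudopopulation(tr, seed = 2)
  res <- train_feature_decoders(P, decoder_config(n_splits = 4, cost_grid = 1,
                                                  seed = 5))
  for (sp in res$splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_identical(sort(c(sp$train, sp$test)), seq_len(nrow(P$rates)))
  }
  # identity switch: applying the trained models to their own source
  # reproduces the native held-out AUC exactly
  res_b <- model_switch(res, P)
  expect_equal(res_b$auc, res$auc)
})

test_that("shuffle null is seeded and centred at chance", {
  s <- coded_bundle()
  tr <- decoding_trials(s, family = "morpheme")
  P <- build_pseudopopulation(tr, seed = 2)
  cfg <- decoder_config(n_splits = 3, cost_grid = 1, seed = 7)
  a <- shuffle_null(P, cfg, n_reps = 8, seed = 99)
  b <- shuffle_null(P, cfg, n_reps = 8, seed = 99)
  expect_identical(a$null_auc, b$null_auc)
  se <- sd(a$null_auc) / sqrt(length(a$null_auc))
  expect_lt(abs(mean(a$null_auc) - 0.5), max(3 * se, 0.05))
})

test_that("smoothed rates conserve spike mass and default to 5/25 ms", {
  r0 <- instantaneous_rates(numeric(0), onsets = c(1, 2))
  expect_true(all(r0 == 0))
  expect_equal(attr(r0, "bin"), 0.005)
  expect_equal(attr(r0, "kernel_sd"), 0.025)

  # one spike in mid-window integrates to ~1 spike
  r1 <- instantaneous_rates(10.25, onsets = 10.5, window = c(-0.5, 0))
  mass <- sum(r1) * attr(r1, "bin")
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_true(all(r1 >= 0))
  expect_identical(ncol(r1), 100L)
})

test_that("disjoint speak/listen populations give chance cross-condition decoding", {
  cfg <- sim_config(
    n_participants = 1, units_range = c(30, 30),
    words_per_participant = 250, listen_words_per_participant = 250,
    n_listen_participants = 1,
    tuned_fractions = c(place = 0.25, syllable = 0, morpheme = 0),
    listen_fraction = 0.25, overlap_fraction = 0, effect_size = 1,
    seed = 77
  )
  s <- simulate_bundle(cfg, n_lexicon = 150)
  tr_speak <- decoding_trials(s, family = "place", window = "planning")
  tr_listen <- decoding_trials(s, family = "place", window = "perception")
  P_s <- build_pseudopopulation(tr_speak, seed = 4)
  P_l <- build_pseudopopulation(tr_listen, seed = 4)
  dcfg <- decoder_config(n_splits = 6, cost_grid = 1, seed = 13)
  res <- train_feature_decoders(P_s, dcfg)
  sw <- model_switch(res, P_l, same_trials = FALSE)
  expect_gte(sw$summary$mean_auc, 0.45)
  expect_lte(sw$summary$mean_auc, 0.55)
})

test_that("temporal decoding flags flat traces as ambiguous", {
  withr::with_seed(31, {
    n <- 60
    rates <- array(1, c(n, 5, 4))   # constant rates, no information
    attr(rates, "time") <- c(-0.4, -0.3, -0.2, -0.1)
    labels <- list(fam = matrix(rbinom(n, 1, 0.5) == 1, ncol = 1))
    cfg <- decoder_config(n_splits = 2, cost_grid = 1, min_positives = 5,
                          seed = 3)
    td <- temporal_decoding(rates, labels, cfg, n_boot = 50, n_perm = 50)
    expect_true(all(td$peaks$ambiguous))
    expect_equal(td$summary$n_ambiguous, 2)
  })
})
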