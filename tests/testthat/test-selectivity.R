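test_that("count assembly applies the window, overlap and rate filters", {
  s <- small_bundle()
  cm <- assemble_counts(s, "planning")
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == floor(cm$counts)))

  # overlap exclusion: every excluded word's planning window does overlap
  exc_ids <- cm$excluded$id[cm$excluded$reason == "planning_overlap"]
  words <- s$words[s$words$condition == "speak", ]
  words <- words[order(words$participant, words$onset_s), ]
  prev_off <- dplyr::lag(words$offset_s, default = -Inf)
  same_part <- dplyr::lag(words$participant) == words$participant
  overlapping <- words$word_id[!is.na(same_part) & same_part &
                                 words$onset_s - 0.5 < prev_off]
  expect_setequal(exc_ids, overlapping)

  # turning off the exclusion keeps all speak words
  cm_all <- assemble_counts(s, "planning", exclude_overlap = FALSE)
  expect_identical(ncol(cm_all$counts),
                   sum(s$words$condition == "speak"))

  # widening the planning window can only grow the excluded set
  cfg2 <- s$config; cfg2$planning_window <- c(-0.8, 0)
  s2 <- s; s2$config <- cfg2
  cm_wide <- assemble_counts(s2, "planning")
  expect_true(all(exc_ids %in% cm_wide$excluded$id))
})

test_that("low-rate units are dropped and logged", {
  s <- small_bundle()
  s$units$mean_rate_hz[1] <- 0.05
  cm <- assemble_counts(s, "planning")
  expect_false(s$units$unit_id[1] %in% cm$unit_ids)
  expect_true(s$units$unit_id[1] %in%
                cm$excluded$id[cm$excluded$reason == "rate_below_min"])
})

test_that("poisson fit recovers the closed-form intercept and flags bad designs", {
  y <- rep(3L, 40)
  f <- fit_poisson_glm(y, cbind(`(Intercept)` = rep(1, 40)))
  expect_equal(unname(coef(f)[1]), log(3), tolerance = 1e-8)

  X <- cbind(`(Intercept)` = 1, a = rnorm(40), b = 0)
  X[, "b"] <- X[, "a"]
  expect_error(fit_poisson_glm(y, X), class = "phonopop_rank_deficient")
  expect_error(fit_poisson_glm(y, X[1:10, ]), "rows")
})

test_that("wald confidence intervals cover planted coefficients at nominal rate", {
  X <- place_design(300)
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- c(log(1.5), rep(0, ncol(X)))
  beta[1 + 4] <- 0.5   # alveolar
  cover <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      y <- rpois(nrow(Xd), exp(as.numeric(Xd %*% beta)))
      f <- fit_poisson_glm(y, Xd)
      se <- sqrt(diag(f$vcov))
      lo <- coef(f) - 1.96 * se; hi <- coef(f) + 1.96 * se
      lo[5] <= 0.5 && 0.5 <= hi[5]
    }, logical(1))
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("AIC follows its definition and nested-difference identity", {
  y <- withr::with_seed(5, rpois(100, 2))
  X <- place_design(100)
  full <- fit_poisson_glm(y, cbind(`(Intercept)` = 1, X))
  rest <- fit_poisson_glm(y, cbind(`(Intercept)` = rep(1, 100)))

  # independent recomputation of llf from mu and y
  llf_oracle <- function(f) sum(f$y * log(f$fitted) - f$fitted - lgamma(f$y + 1))
  expect_equal(model_aic(full), 2 * full$k - 2 * llf_oracle(full),
               tolerance = 1e-10)
  expect_equal(model_aic(full) - model_aic(rest),
               2 * (full$k - rest$k) - 2 * (full$llf - rest$llf),
               tolerance = 1e-10)
})

test_that("D-squared matches the deviance-ratio oracle and its identities", {
  # independent deviance routine (Kullback-Leibler form)
  dev_oracle <- function(y, mu) {
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y - mu))
  }
  X <- place_design(120)
  withr::with_seed(31, {
    for (i in 1:20) {
      beta <- c(log(1.5), rnorm(ncol(X), 0, 0.3))
      Xd <- cbind(`(Intercept)` = 1, X)
      y <- rpois(nrow(Xd), exp(as.numeric(Xd %*% beta)))
      full <- fit_poisson_glm(y, Xd)
      rest <- fit_poisson_glm(y, Xd[, 1, drop = FALSE])
      d2 <- d_squared(full, rest)
      expect_gte(d2, 0); expect_lte(d2, 1)
      expect_equal(d2, 1 - dev_oracle(y, full$fitted) / dev_oracle(y, rest$fitted),
                   tolerance = 1e-10)
      # LRT statistic equals the deviance difference
      lrt <- likelihood_ratio_test(full, rest)
      expect_equal(lrt$statistic,
                   dev_oracle(y, rest$fitted) - dev_oracle(y, full$fitted),
                   tolerance = 1e-8)
    }
  })

  # identical fits give 0; a saturated full model gives 1
  y <- withr::with_seed(3, rpois(60, 3)) + 1L  # keep y > 0 so saturation is exact
  rest <- fit_poisson_glm(y, cbind(`(Intercept)` = rep(1, 60)))
  expect_equal(d_squared(rest, rest), 0)
  sat <- fit_poisson_glm(y, cbind(`(Intercept)` = 1,
                                  stats::model.matrix(~ 0 + factor(seq_len(60)))[, -1]))
  expect_equal(d_squared(sat, rest), 1, tolerance = 1e-8)

  # restricted model that saturates is flagged undefined
  d_na <- d_squared(rest, rest_sat <- sat)
  expect_true(is.na(d_na))
  expect_identical(attr(d_na, "reason"), "restricted_saturated")
})

test_that("likelihood-ratio test: identities, df and non-nested rejection", {
  y <- withr::with_seed(9, rpois(80, 2))
  X <- place_design(80)
  full <- fit_poisson_glm(y, cbind(`(Intercept)` = 1, X))
  rest <- fit_poisson_glm(y, cbind(`(Intercept)` = rep(1, 80)))
  lrt <- likelihood_ratio_test(full, rest)
  expect_identical(lrt$df, ncol(X))
  expect_gte(lrt$statistic, 0)

  same <- likelihood_ratio_test(
    fit_poisson_glm(y, cbind(`(Intercept)` = 1, x = X[, 4])), rest)
  expect_identical(same$df, 1L)

  expect_error(likelihood_ratio_test(rest, full),
               class = "phonopop_not_nested")
})

test_that("wald selectivity has the right bonferroni factor and power", {
  X <- place_design(600)
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- c(log(1.5), rep(0, 10)); beta[1 + 7] <- 1  # velar
  flags <- withr::with_seed(55, {
    vapply(1:50, function(i) {
      y <- rpois(nrow(Xd), exp(as.numeric(Xd %*% beta)))
      f <- fit_poisson_glm(y, Xd)
      w <- wald_selectivity(f, colnames(X))
      expect_equal(w$p.adjusted, pmin(w$p.value * 10, 1))
      w$tuned[w$term == "velar"]
    }, logical(1))
  })
  expect_gte(mean(flags), 0.95)
})

test_that("preferred composition is the sign vector and maximizes the fitted rate", {
  X <- place_design(500)
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- c(log(2), withr::with_seed(8, sample(c(-0.8, 0.8), 10, replace = TRUE)))
  y <- withr::with_seed(12, rpois(nrow(Xd), exp(as.numeric(Xd %*% beta))))
  f <- fit_poisson_glm(y, Xd)
  pref <- preferred_composition(f)
  expect_true(all(pref %in% c(-1L, 0L, 1L)))

  # brute force over all 2^10 binary compositions: the argmax of the
  # predicted rate is the composition matching the sign vector
  b <- coef(f)[-1]
  comps <- as.matrix(expand.grid(rep(list(0:1), 10)))
  pred <- comps %*% b
  best <- comps[which.max(pred), ]
  expect_identical(unname(as.integer(best)), unname(as.integer(pref == 1)))

  # sign vector of explicit coefficients
  f2 <- list(coefficients = c(`(Intercept)` = 1, a = 0.8, b = -0.3, c = 0),
             vcov = diag(4))
  class(f2) <- "poisson_fit"
  expect_identical(unname(preferred_composition(f2)), c(1L, -1L, 0L))
})

test_that("tuning curves fall with hamming distance for compositional neurons", {
  X <- place_design(600)
  v <- withr::with_seed(2, sample(c(-1L, 1L), 10, replace = TRUE))
  # compositional neuron: rate decays with distance from its preferred
  # composition (half a log-unit per position)
  signed <- ifelse(X > 0, 1L, -1L)
  d <- rowSums(signed != matrix(v, nrow(X), 10, byrow = TRUE))
  withr::with_seed(14, {
    y <- rpois(nrow(X), exp(log(5) + 0.5 * (max(d) - d)))
    z <- (y - mean(y)) / sd(y)
    tc <- tuning_curve(z, X, v)
    expect_lt(attr(tc, "rho"), -0.8)
    expect_true(all(diff(tc$distance) > 0))

    # null neurons: |rho| small in at least 95% of replicates
    small <- vapply(1:60, function(i) {
      y0 <- rpois(nrow(X), 2)
      z0 <- (y0 - mean(y0)) / sd(y0)
      abs(attr(tuning_curve(z0, X, v), "rho")) <= 0.2
    }, logical(1))
    expect_gte(mean(small), 0.95)
  })

  # degenerate: all words identical -> single bin, rho missing
  X1 <- X[rep(1, 30), ]
  tc1 <- tuning_curve(rnorm(30), X1, v)
  expect_identical(nrow(tc1), 1L)
  expect_true(is.na(attr(tc1, "rho")))
})

test_that("syllable-control comparison separates true syllable coding", {
  # planted syllable neurons respond to contains_syllable words only
  withr::with_seed(33, {
    n_neuron <- 12; n_word <- 60
    cats <- c("contains_syllable", "phonemes_without_syllable",
              "different_phonemes", "same_phonemes_diff_order")
    df <- do.call(rbind, lapply(seq_len(n_neuron), function(g) {
      cat_w <- sample(cats, n_word, replace = TRUE)
      z <- rnorm(n_word) + (cat_w == "contains_syllable") * 1.2
      data.frame(neuron = g, zrate = z, category = cat_w)
    }))
    res <- syllable_control_comparison(df)
    expect_true(all(res$tests$mean_difference > 0))
    expect_true(all(res$tests$p.value < 0.01))

    # order-free phoneme coding: contrast with phonemes_without_syllable
    # centred at zero
    df0 <- do.call(rbind, lapply(seq_len(n_neuron), function(g) {
      cat_w <- sample(cats, n_word, replace = TRUE)
      has_phon <- cat_w %in% c("contains_syllable", "phonemes_without_syllable",
                               "same_phonemes_diff_order")
      data.frame(neuron = g, zrate = rnorm(n_word) + has_phon * 1.2,
                 category = cat_w)
    }))
    res0 <- syllable_control_comparison(df0)
    d <- res0$tests$mean_difference[res0$tests$category ==
                                      "phonemes_without_syllable"]
    expect_lt(abs(d), 0.5)
  })

  # identical rates everywhere: zero differences, p = 1
  df_eq <- expand.grid(neuron = 1:6,
                       category = c("contains_syllable", "different_phonemes"))
  df_eq$zrate <- 1
  res_eq <- syllable_control_comparison(df_eq)
  expect_equal(res_eq$tests$mean_difference, 0)
  expect_equal(res_eq$tests$p.value, 1)
})

test_that("hypergeometric overlap test matches enumeration", {
  res <- overlap_test(5, 5, 5, 10)
  expect_equal(res$p.value, 2 / choose(10, 5), tolerance = 1e-12)
  # overlap at expectation: p near 1
  res_mid <- overlap_test(10, 10, 5, 20)
  expect_gt(res_mid$p.value, 0.5)
  expect_equal(res_mid$expected, 5)
  # empty set A
  expect_equal(overlap_test(0, 5, 0, 10)$p.value, 1)
  expect_error(overlap_test(5, 5, 6, 10), class = "phonopop_bad_counts")
})

test_that("spatial trend test has bins-1 df and detects planted gradients", {
  withr::with_seed(60, {
    bins <- rep(1:5, each = 60)
    p_tuned <- seq(0.05, 0.5, length.out = 5)[bins]
    tuned <- runif(300) < p_tuned
    res <- spatial_trend(tuned, bins)
    expect_equal(res$df, 4)
    expect_lt(res$p.value, 0.01)

    flat <- runif(300) < 0.2
    res_flat <- spatial_trend(flat, bins)
    expect_gt(res_flat$p.value, 0.01)
  })
})

test_that("z-scored rates standardize per neuron to machine precision", {
  s <- small_bundle()
  cm <- assemble_counts(s, "planning")
  z <- phonopop:::zscore_counts(cm)
  ok <- !apply(is.na(z), 1, any)
  expect_true(any(ok))
  expect_true(all(abs(rowMeans(z[ok, , drop = FALSE])) < 1e-12))
  expect_true(all(abs(apply(z[ok, , drop = FALSE], 1, var) - 1) < 1e-12))
})

test_that("tuned-set recovery overlaps the planted set strongly", {
  s <- coded_bundle()
  gt <- s$ground_truth
  sel <- neuron_selectivity(s, families = "place")
  planted <- s$units$unit_id[s$units$neuron %in% which(gt$tuned[, "place"])]
  flagged <- sel$unit_id[sel$tuned]
  jaccard <- length(intersect(planted, flagged)) /
    length(union(planted, flagged))
  expect_gte(jaccard, 0.8)
})
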