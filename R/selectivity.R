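#' Per-neuron encoding analysis across feature families
#'
#' Fits, for every included unit and every requested feature family, the
#' full Poisson encoding model (intercept + family regressors; morphology
#' models also carry the word-length covariate `n_phonemes`) and its
#' restricted counterpart, and derives the selectivity statistics: the
#' likelihood-ratio test at `alpha`, the deviance-based D-squared, AIC of
#' both models, per-dimension Wald tests (Bonferroni corrected within the
#' family) and the preferred-composition sign vector.
#'
#' @param session A `session_bundle`.
#' @param families Feature families to analyse (subset of
#'   `place`, `manner`, `cardinal`, `syllable`, `morpheme`).
#' @param window Analysis window (see [assemble_counts()]).
#' @param alpha Likelihood-ratio significance level.
#' @param exclude_overlap,min_rate_hz Passed to [assemble_counts()].
#' @return A tibble of class `selectivity_result`, one row per unit x
#'   family: test statistics, `tuned` flag, `d_squared`, AICs, and
#'   list-columns `wald` (per-dimension tibble) and `preferred` (sign
#'   vector). The count matrix is attached as attribute `counts`.
#' @export
neuron_selectivity <- function(session,
                               families = c("place", "syllable", "morpheme"),
                               window = "planning", alpha = 0.01,
                               exclude_overlap = TRUE, min_rate_hz = 0.1) {
  cm <- assemble_counts(session, window = window,
                        exclude_overlap = exclude_overlap,
                        min_rate_hz = min_rate_hz)
  X <- session_designs(session, cm)
  families <- intersect(families, names(X$design))

  rows <- list()
  for (u in seq_along(cm$unit_ids)) {
    y <- cm$counts[u, ]
    for (f in families) {
      Xf <- X$design[[f]]
      nuis <- if (f == "morpheme") cbind(n_phonemes = X$n_phonemes) else NULL
      X_full <- cbind(`(Intercept)` = 1, nuis, Xf)
      X_rest <- cbind(`(Intercept)` = rep(1, length(y)), nuis)

      res <- tryCatch({
        full <- fit_poisson_glm(y, X_full)
        rest <- fit_poisson_glm(y, X_rest)
        lrt <- likelihood_ratio_test(full, rest, alpha = alpha)
        wald <- wald_selectivity(full, colnames(Xf), alpha = alpha)
        pref <- preferred_composition(
          full, exclude = setdiff(colnames(X_full), colnames(Xf)))
        tibble(
          unit_id = cm$unit_ids[u], family = f,
          statistic = lrt$statistic, df = lrt$df, p.value = lrt$p.value,
          tuned = lrt$significant,
          d_squared = d_squared(full, rest),
          aic_full = model_aic(full), aic_restricted = model_aic(rest),
          any_wald_tuned = any(wald$tuned),
          wald = list(wald), preferred = list(pref), converged = TRUE
        )
      }, phonopop_rank_deficient = function(e) NULL,
         phonopop_no_convergence = function(e) {
           tibble(unit_id = cm$unit_ids[u], family = f,
                  statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                  tuned = FALSE, d_squared = NA_real_, aic_full = NA_real_,
                  aic_restricted = NA_real_, any_wald_tuned = FALSE,
                  wald = list(NULL), preferred = list(NULL), converged = FALSE)
         })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- bind_rows(rows)
  attr(out, "counts") <- cm
  attr(out, "alpha") <- alpha
  attr(out, "window") <- window
  class(out) <- c("selectivity_result", class(out))
  out
}

# Per-family design matrices for the words retained in a count matrix.
# Simulated bundles carry their feature space and per-word lexicon indices;
# sessions loaded from disk are embedded afresh from their word forms.
session_designs <- function(session, cm) {
  fs <- session$feature_space
  if (!is.null(fs) && "lexicon_index" %in% names(cm$words)) {
    idx <- cm$words$lexicon_index
    list(
      design = lapply(fs$design, function(M) M[idx, , drop = FALSE]),
      n_phonemes = fs$n_phonemes[idx]
    )
  } else {
    fs <- feature_space(table_to_words(cm$words))
    list(design = fs$design, n_phonemes = fs$n_phonemes)
  }
}

#' Hamming-distance tuning curve of a neuron
#'
#' Bins a neuron's per-word z-scored rates by the Hamming distance between
#' each word and the neuron's preferred composition, and quantifies the
#' monotone fall-off with Spearman's rank correlation across words. Words
#' are encoded as signed presence (+1 where the word contains the feature,
#' -1 where it does not) so that distance 0 is the composition maximizing
#' the fitted rate.
#'
#' @param zrates Per-word z-scored rates of one neuron.
#' @param word_vectors Matrix words x dims of feature counts (or binary
#'   indicators) in the same family as `preferred`.
#' @param preferred Sign vector from [preferred_composition()].
#' @return Tibble of class `tuning_curve` (columns `distance`, `mean_z`,
#'   `sem`, `n_words`) with attributes `rho`, `p.value` (Spearman, across
#'   words; `NA` with fewer than 3 distinct distances) and `distances`.
#' @export
tuning_curve <- function(zrates, word_vectors, preferred) {
  word_vectors <- as.matrix(word_vectors)
  assert_that(nrow(word_vectors) == length(zrates),
              "one z-scored rate per word required")
  assert_that(ncol(word_vectors) == length(preferred),
              "preferred vector length must match feature dimensions")
  signed <- ifelse(word_vectors > 0, 1L, -1L)
  d <- rowSums(signed != matrix(preferred, nrow(signed), length(preferred),
                                byrow = TRUE))

  curve <- tibble(distance = d, z = zrates) %>%
    group_by(.data$distance) %>%
    summarise(mean_z = mean(.data$z),
              sem = sd(.data$z) / sqrt(n()),
              n_words = n(), .groups = "drop") %>%
    arrange(.data$distance)

  if (length(unique(d)) >= 3) {
    ct <- suppressWarnings(cor.test(d, zrates, method = "spearman",
                                    exact = FALSE))
    rho <- unname(ct$estimate); pv <- ct$p.value
  } else {
    rho <- NA_real_; pv <- NA_real_
  }
  attr(curve, "rho") <- rho
  attr(curve, "p.value") <- pv
  attr(curve, "distances") <- d
  class(curve) <- c("tuning_curve", class(curve))
  curve
}

#' Preferred-syllable control comparison
#'
#' For neurons with a preferred syllable, compares the mean z-scored rate
#' for words containing that syllable against each control word category
#' (same phonemes without the syllable, different phonemes, same phonemes
#' across a segmentation boundary, same phonemes in a different order)
#' with a paired two-sided Wilcoxon signed-rank test across neurons.
#'
#' @param data Long tibble with columns `neuron`, `zrate`, `category`
#'   (category labels as produced by [classify_syllable_control()]).
#' @param min_neurons Minimum neurons contributing a preferred-syllable
#'   mean (default 5).
#' @return List with `neuron_means` (neuron x category tibble) and `tests`
#'   (per control category: paired mean difference, n and Wilcoxon p).
#' @export
syllable_control_comparison <- function(data, min_neurons = 5) {
  stopifnot(all(c("neuron", "zrate", "category") %in% names(data)))
  means <- data %>%
    group_by(.data$neuron, .data$category) %>%
    summarise(mean_z = mean(.data$zrate), .groups = "drop")
  with_pref <- means %>% filter(.data$category == "contains_syllable")
  assert_that(nrow(with_pref) >= min_neurons,
              sprintf("need >= %d neurons with a preferred syllable",
                      min_neurons))

  controls <- setdiff(unique(means$category), "contains_syllable")
  tests <- lapply(controls, function(cc) {
    paired <- with_pref %>%
      rename(z_pref = "mean_z") %>%
      select("neuron", "z_pref") %>%
      dplyr::inner_join(
        means %>% filter(.data$category == cc) %>%
          rename(z_ctrl = "mean_z") %>% select("neuron", "z_ctrl"),
        by = "neuron"
      )
    if (nrow(paired) == 0) {
      return(tibble(category = cc, n = 0L, mean_difference = NA_real_,
                    p.value = NA_real_))
    }
    diffs <- paired$z_pref - paired$z_ctrl
    p <- if (all(diffs == 0)) 1 else {
      suppressWarnings(wilcox.test(paired$z_pref, paired$z_ctrl,
                                   paired = TRUE)$p.value)
    }
    tibble(category = cc, n = nrow(paired),
           mean_difference = mean(diffs), p.value = p)
  })
  list(neuron_means = means, tests = bind_rows(tests))
}

#' Two-sided hypergeometric overlap test
#'
#' Tests whether the observed overlap between two tuned subpopulations of
#' sizes `nA` and `nB` drawn from `N` units is larger or smaller than
#' expected by chance; two-sided p is twice the smaller tail, capped at 1.
#'
#' @param nA,nB Sizes of the two sets.
#' @param nAB Observed overlap.
#' @param N Population size.
#' @return List with `p.value`, `observed`, `expected`.
#' @export
#' @examples
#' overlap_test(5, 5, 5, 10)$p.value  # 2/choose(10, 5) capped tail
overlap_test <- function(nA, nB, nAB, N) {
  ok <- nAB <= min(nA, nB) && max(nA, nB) <= N &&
    nAB >= max(0, nA + nB - N) && min(nA, nB, nAB, N) >= 0
  assert_that(ok, "inconsistent overlap counts",
              class = "phonopop_bad_counts")
  upper <- stats::phyper(nAB - 1, nA, N - nA, nB, lower.tail = FALSE)
  lower <- stats::phyper(nAB, nA, N - nA, nB)
  list(p.value = min(1, 2 * min(lower, upper)),
       observed = nAB, expected = nA * nB / N)
}

#' Chi-squared trend of tuned proportions across position bins
#'
#' Homogeneity test of the proportion of tuned units across anatomical
#' bins (cortical depth or rostro-caudal position); `df = bins - 1`.
#' Bins without units are merged into their lower neighbour.
#'
#' @param tuned Logical vector, one per unit.
#' @param bin Position bin per unit (integer or factor).
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n_bins`.
#' @export
spatial_trend <- function(tuned, bin) {
  assert_that(length(tuned) == length(bin), "tuned and bin lengths differ")
  bin <- as.integer(factor(bin))
  tab <- table(factor(bin, levels = sort(unique(bin))), factor(tuned, levels = c(FALSE, TRUE)))
  # merge empty bins downward
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  assert_that(nrow(tab) >= 2, "need at least two non-empty bins")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = unname(res$p.value), n_bins = nrow(tab))
}
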