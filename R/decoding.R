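#' Decoder configuration
#'
#' Settings for the per-dimension support-vector decoders: random 75/25
#' train/test splits repeated `n_splits` times; a radial-basis-function
#' kernel whose coefficient defaults to 1/(number of neurons); and a
#' regularization constant `C` chosen per classifier by cross-validation
#' nested in the training set (a length-1 `cost_grid` fixes `C` and skips
#' the nested search).
#'
#' @param train_fraction Fraction of trials used for training.
#' @param n_splits Number of random train/test splits.
#' @param gamma RBF kernel coefficient; `NULL` means 1/n_neurons.
#' @param cost_grid Candidate `C` values for the nested search.
#' @param nested_folds Folds of the nested cross-validation.
#' @param min_positives Minimum positive training trials required to train
#'   a dimension's classifier; dimensions below it are skipped and logged.
#' @param seed Seed for the split stream.
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(train_fraction = 0.75, n_splits = 50,
                           gamma = NULL,
                           cost_grid = c(0.01, 0.1, 1, 10, 100),
                           nested_folds = 5, min_positives = 10,
                           seed = 1) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  assert_that(length(cost_grid) >= 1 && all(cost_grid > 0),
              "cost_grid must be non-empty and positive")
  structure(
    list(train_fraction = train_fraction, n_splits = n_splits,
         gamma = gamma, cost_grid = cost_grid, nested_folds = nested_folds,
         min_positives = min_positives, seed = as.integer(seed)),
    class = "decoder_config"
  )
}

#' Rank-based ROC-AUC
#'
#' Area under the receiver operating characteristic computed from ranks
#' (the Mann-Whitney statistic), with tied scores counted one half. A
#' constant score gives 0.5; scores equal to the labels give 1.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (logical, or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' score_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))  # 0.5
score_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to score AUC",
          class = "phonopop_one_class")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Trial-matched pseudopopulation across participants
#'
#' Combines units recorded in different participants into one
#' pseudopopulation by matching words on their feature-label pattern: for
#' every distinct pattern the number of pseudo-trials is the minimum count
#' of that pattern across participants, and each participant contributes
#' that many of its own (randomly chosen, never reused) words. No trial or
#' neural data is duplicated or upsampled; patterns absent in any
#' participant are dropped and logged.
#'
#' @param trials Tibble with one row per word: `participant`, `word_id`,
#'   label columns (prefix `label_`, logical/0-1) and unit rate columns
#'   (prefix `u_`).
#' @param seed Seed for within-participant assignment.
#' @return Object of class `pseudopopulation`: `rates` (trials x neurons
#'   matrix), `labels` (trials x dimensions logical matrix), `provenance`
#'   (tibble of the (participant, word_id) pairs behind every trial) and
#'   `matching_log`.
#' @export
build_pseudopopulation <- function(trials, seed = 1) {
  lab_cols <- grep("^label_", names(trials), value = TRUE)
  unit_cols <- grep("^u_", names(trials), value = TRUE)
  assert_that(length(lab_cols) > 0, "no label_ columns")
  assert_that(length(unit_cols) > 0, "no u_ rate columns")

  participants <- sort(unique(trials$participant))
  lab_mat <- as.matrix(trials[lab_cols]) > 0
  pattern <- apply(lab_mat, 1, paste, collapse = "")

  if (length(participants) == 1) {
    rates <- as.matrix(trials[unit_cols])
    # single session: identity pass-through, trials are the words
    out <- list(
      rates = rates, labels = lab_mat,
      provenance = tibble(trial = seq_len(nrow(trials)),
                          participant = trials$participant,
                          word_id = trials$word_id),
      matching_log = tibble(pattern = character(0), reason = character(0)),
      dims = sub("^label_", "", lab_cols)
    )
    class(out) <- "pseudopopulation"
    return(out)
  }

  counts <- table(pattern, trials$participant)
  n_match <- apply(counts, 1, min)
  dropped <- names(n_match)[n_match == 0]
  kept <- names(n_match)[n_match > 0]

  with_seed(seed, {
    per_part <- lapply(participants, function(p) {
      rows_p <- which(trials$participant == p)
      unlist(lapply(kept, function(pt) {
        cand <- rows_p[pattern[rows_p] == pt]
        # sample() would misbehave on a length-1 candidate set
        cand[sample.int(length(cand), n_match[[pt]])]
      }))
    })
  })

  # participant blocks are column-bound: row j of each block shares a
  # pattern; each block contributes only the units with data for that
  # participant (other participants' units are NA-masked)
  rates <- do.call(cbind, lapply(seq_along(participants), function(i) {
    block <- as.matrix(trials[per_part[[i]], unit_cols])
    block[, colSums(is.na(block)) == 0, drop = FALSE]
  }))
  assert_that(!anyNA(rates), "unit columns with partial data")
  first <- per_part[[1]]
  labels <- lab_mat[first, , drop = FALSE]

  prov <- bind_rows(lapply(seq_along(participants), function(i) {
    tibble(trial = seq_along(per_part[[i]]),
           participant = participants[i],
           word_id = trials$word_id[per_part[[i]]])
  }))
  assert_that(anyDuplicated(prov[c("participant", "word_id")]) == 0,
              "internal error: duplicated trials in pseudopopulation")

  out <- list(
    rates = rates, labels = labels, provenance = prov,
    matching_log = tibble(pattern = dropped,
                          reason = rep("absent_in_some_participant",
                                       length(dropped))),
    dims = sub("^label_", "", lab_cols)
  )
  class(out) <- "pseudopopulation"
  out
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat("<pseudopopulation>", nrow(x$rates), "trials x", ncol(x$rates),
      "neurons;", ncol(x$labels), "label dimensions\n")
  invisible(x)
}

#' Per-word decoding trials for one session
#'
#' Builds the wide trial table consumed by [build_pseudopopulation()]:
#' window spike counts per unit plus binary presence labels for each
#' dimension of the requested feature family.
#'
#' @param session A `session_bundle`.
#' @param family Feature family for the labels.
#' @param window Analysis window (see [assemble_counts()]).
#' @param ... Passed to [assemble_counts()].
#' @return Wide tibble: `participant`, `word_id`, `label_*`, `u_*`.
#' @export
decoding_trials <- function(session, family = "place", window = "planning",
                            ...) {
  cm <- assemble_counts(session, window = window, ...)
  X <- session_designs(session, cm)
  assert_that(family %in% names(X$design), "unknown feature family")
  lab <- family_labels(X$design[[family]], family)
  rates <- t(cm$counts)
  colnames(rates) <- paste0("u_", rownames(cm$counts))
  # a unit carries data only for its own participant's words
  unit_part <- cm$units$participant[match(rownames(cm$counts),
                                          cm$units$unit_id)]
  foreign <- outer(cm$words$participant, unit_part, `!=`)
  rates[foreign] <- NA_real_
  bind_cols(
    tibble(participant = cm$words$participant, word_id = cm$words$word_id),
    as_tibble(lab), as_tibble(rates)
  )
}

# Binary decoding labels of a family's design block. Morphology uses one
# any-bound-morpheme classifier; other families one classifier per dimension.
family_labels <- function(design, family) {
  if (family == "morpheme") {
    lab <- matrix(rowSums(design > 0) > 0, ncol = 1,
                  dimnames = list(NULL, "label_morpheme"))
  } else {
    lab <- design > 0
    colnames(lab) <- paste0("label_", colnames(design))
  }
  lab
}

# Fit one RBF-SVM and return decision scores for newdata, oriented so that
# larger scores mean the positive class.
svm_scores <- function(x_train, y_train, x_test, gamma, cost) {
  fit <- e1071::svm(x_train, factor(y_train, levels = c(FALSE, TRUE)),
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  decision_scores(fit, x_test)
}

# Nested cross-validated choice of C by mean AUC on the training set.
select_cost <- function(x, y, cfg, gamma) {
  if (length(cfg$cost_grid) == 1) return(cfg$cost_grid)
  folds <- sample(rep_len(seq_len(cfg$nested_folds), length(y)))
  aucs <- vapply(cfg$cost_grid, function(cost) {
    mean(vapply(seq_len(cfg$nested_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        return(NA_real_)
      }
      sc <- svm_scores(x[tr, , drop = FALSE], y[tr],
                       x[!tr, , drop = FALSE], gamma, cost)
      score_auc(sc, y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cfg$cost_grid[which.max(aucs)]
}

#' Train per-dimension feature decoders on a pseudopopulation
#'
#' For each feature dimension, trains one binary RBF-SVM per random
#' train/test split to predict whether the upcoming word contains that
#' feature, and scores it on the held-out trials with ROC-AUC. Dimensions
#' with too few positive training instances are skipped and logged; the
#' per-split decoding score of the family is the mean AUC over its trained
#' dimensions.
#'
#' @param P A `pseudopopulation`.
#' @param cfg A [decoder_config()].
#' @param keep_models Retain fitted models for [model_switch()].
#' @return Object of class `decoder_result`: `auc` (tibble dim x split),
#'   `split_mean` (per-split mean AUC), `summary` (mean, sd), `skipped`,
#'   and the split indices.
#' @export
train_feature_decoders <- function(P, cfg = decoder_config(),
                                   keep_models = TRUE) {
  stopifnot(inherits(P, "pseudopopulation"))
  n <- nrow(P$rates)
  assert_that(n >= 20, "need at least 20 pseudo-trials")
  gamma <- cfg$gamma %||% (1 / ncol(P$rates))
  x_all <- P$rates

  with_seed(cfg$seed, {
    splits <- lapply(seq_len(cfg$n_splits), function(s) {
      tr <- sample.int(n, round(cfg$train_fraction * n))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })

    dims <- P$dims
    skipped <- character(0)
    trainable <- vapply(seq_along(dims), function(d) {
      y <- P$labels[, d]
      sum(y) * cfg$train_fraction >= cfg$min_positives &&
        sum(!y) * cfg$train_fraction >= 2
    }, logical(1))
    skipped <- dims[!trainable]
    assert_that(any(trainable), "all label dimensions were skipped",
                class = "phonopop_all_skipped")

    auc <- matrix(NA_real_, length(dims), cfg$n_splits,
                  dimnames = list(dims, NULL))
    models <- if (keep_models) {
      lapply(seq_along(dims), function(d) vector("list", cfg$n_splits))
    }
    for (d in which(trainable)) {
      y <- P$labels[, d]
      for (s in seq_along(splits)) {
        tr <- splits[[s]]$train; te <- splits[[s]]$test
        if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
        cost <- select_cost(x_all[tr, , drop = FALSE], y[tr], cfg, gamma)
        fit <- e1071::svm(x_all[tr, , drop = FALSE],
                          factor(y[tr], levels = c(FALSE, TRUE)),
                          kernel = "radial", gamma = gamma, cost = cost,
                          scale = FALSE)
        sc <- decision_scores(fit, x_all[te, , drop = FALSE])
        auc[d, s] <- score_auc(sc, y[te])
        if (keep_models) models[[d]][[s]] <- fit
      }
    }

    split_mean <- colMeans(auc[trainable, , drop = FALSE], na.rm = TRUE)
    out <- list(
      auc = auc, split_mean = split_mean,
      summary = tibble(mean_auc = mean(split_mean, na.rm = TRUE),
                       sd_auc = sd(split_mean)),
      skipped = skipped, splits = splits, dims = dims,
      trainable = trainable, gamma = gamma, cfg = cfg,
      models = models, labels = P$labels
    )
    class(out) <- "decoder_result"
    out
  })
}

# Decision values oriented so larger = positive class (TRUE).
decision_scores <- function(fit, x_new) {
  pr <- stats::predict(fit, x_new, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "TRUE")) 1 else -1
  sgn * dv[, 1]
}

#' @export
print.decoder_result <- function(x, ...) {
  cat("<decoder_result>", sum(x$trainable), "of", length(x$dims),
      "dimensions;", length(x$split_mean), "splits; mean AUC",
      sprintf("%.3f +/- %.3f", x$summary$mean_auc, x$summary$sd_auc), "\n")
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname train_feature_decoders
#' @param x,object A `decoder_result`.
#' @param ... Unused.
#' @method tidy decoder_result
#' @export
tidy.decoder_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$auc, responseName = "auc",
                                stringsAsFactors = FALSE)) %>%
    stats::setNames(c("dimension", "split", "auc")) %>%
    mutate(split = as.integer(factor(.data$split,
                                     levels = unique(.data$split)))) %>%
    filter(!is.na(.data$auc))
}

#' @rdname train_feature_decoders
#' @method glance decoder_result
#' @export
glance.decoder_result <- function(x, ...) {
  bind_cols(x$summary,
            tibble(n_splits = length(x$split_mean),
                   n_dims_trained = sum(x$trainable),
                   n_dims_skipped = length(x$skipped),
                   gamma = x$gamma))
}

#' Label-shuffle null distribution of decoding scores
#'
#' Permutes trial labels within participant and reruns the full
#' train/test decoding pipeline, giving the distribution of mean AUC
#' expected when rates carry no label information.
#'
#' @param P A `pseudopopulation`.
#' @param cfg A [decoder_config()].
#' @param n_reps Number of shuffle repetitions.
#' @param seed Seed for the permutation stream.
#' @return Object of class `decoder_null`: numeric `null_auc` of length
#'   `n_reps` plus quantile helpers.
#' @export
shuffle_null <- function(P, cfg = decoder_config(), n_reps = 100,
                         seed = cfg$seed + 1L) {
  stopifnot(inherits(P, "pseudopopulation"))
  # a pseudo-trial couples one word from every participant, so permuting
  # pseudo-trial label rows permutes labels within each participant
  null_auc <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      Pr <- P
      perm <- sample.int(nrow(P$labels))
      Pr$labels <- P$labels[perm, , drop = FALSE]
      cfg_r <- cfg
      cfg_r$seed <- derive_seed(seed, paste0("rep", r))
      res <- train_feature_decoders(Pr, cfg_r, keep_models = FALSE)
      mean(res$split_mean, na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(null_auc = null_auc, n_reps = n_reps),
            class = "decoder_null")
}

#' @export
print.decoder_null <- function(x, ...) {
  cat("<decoder_null>", x$n_reps, "reps; mean",
      sprintf("%.3f", mean(x$null_auc)), "| 97.5th pct",
      sprintf("%.3f", quantile(x$null_auc, 0.975)), "\n")
  invisible(x)
}

#' Cross-condition / cross-epoch model switching
#'
#' Applies decoders trained in one condition or epoch (e.g. word
#' production) to pseudopopulation data from another (e.g. planning, or
#' listening), per dimension and split. When the target shares the source's
#' trial structure, evaluation is restricted to each split's held-out
#' trials so training and testing trials stay disjoint; when the target is
#' an entirely different trial set, all its trials are used.
#'
#' @param trained A `decoder_result` with retained models.
#' @param P_b Target `pseudopopulation` (same neuron set).
#' @param same_trials Target rows correspond one-to-one to source trials
#'   (default: inferred from matching trial counts).
#' @return A `decoder_result` for the switched evaluation.
#' @export
model_switch <- function(trained, P_b, same_trials = NULL) {
  stopifnot(inherits(trained, "decoder_result"),
            inherits(P_b, "pseudopopulation"))
  assert_that(!is.null(trained$models), "retrain with keep_models = TRUE")
  ref_fit <- trained$models[[which(trained$trainable)[1]]][[1]]
  assert_that(identical(ncol(P_b$rates), ncol(ref_fit$SV)),
              "neuron sets of the two conditions differ",
              class = "phonopop_neuron_mismatch")
  same_trials <- same_trials %||% (nrow(P_b$rates) ==
                                     length(trained$splits[[1]]$train) +
                                     length(trained$splits[[1]]$test))

  dims <- trained$dims
  auc <- matrix(NA_real_, length(dims), length(trained$splits),
                dimnames = list(dims, NULL))
  for (d in which(trained$trainable)) {
    y <- P_b$labels[, d]
    for (s in seq_along(trained$splits)) {
      fit <- trained$models[[d]][[s]]
      if (is.null(fit)) next
      rows <- if (same_trials) trained$splits[[s]]$test else seq_len(nrow(P_b$rates))
      if (length(unique(y[rows])) < 2) next
      sc <- decision_scores(fit, P_b$rates[rows, , drop = FALSE])
      auc[d, s] <- score_auc(sc, y[rows])
    }
  }
  split_mean <- colMeans(auc[trained$trainable, , drop = FALSE], na.rm = TRUE)
  out <- list(
    auc = auc, split_mean = split_mean,
    summary = tibble(mean_auc = mean(split_mean, na.rm = TRUE),
                     sd_auc = sd(split_mean)),
    skipped = trained$skipped, splits = trained$splits, dims = dims,
    trainable = trained$trainable, gamma = trained$gamma, cfg = trained$cfg,
    models = NULL, labels = P_b$labels
  )
  class(out) <- "decoder_result"
  out
}
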