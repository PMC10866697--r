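#' Configuration of the synthetic-session generator
#'
#' Collects every knob of the generative model in one validated list. The
#' defaults describe the study conditions the generator emulates: five
#' participants contributing 16-115 single units each and roughly 850
#' produced words each; spike counts in 500 ms planning/production windows
#' that are Poisson with log-rates linear in the word's articulatory
#' features; a fifth of units tuned to places of articulation, a quarter to
#' syllable templates and about a tenth to bound morphemes; per-family
#' response latencies inside the planning window ordered
#' morpheme (-400 ms) before phoneme (-200 ms) before syllable (-80 ms);
#' and largely disjoint speaking- vs listening-tuned subpopulations
#' (7.9% shared).
#'
#' @param n_participants Number of participants.
#' @param units_range Range (min, max) of units per participant, sampled
#'   uniformly.
#' @param words_per_participant Produced (speak-condition) words each.
#' @param listen_words_per_participant Heard words for the perception
#'   control (0 disables; applies to the first `n_listen_participants`).
#' @param n_listen_participants Participants with a perception block.
#' @param planning_window,production_window,perception_window Half-open
#'   analysis windows in seconds relative to word onset.
#' @param tuned_fractions Named fractions of units tuned per feature family.
#' @param family_assignment `"independent"` samples each family's tuned set
#'   independently (multi-feature neurons arise by chance, as observed in
#'   cortex); `"disjoint"` partitions tuned sets so each neuron carries at
#'   most one family.
#' @param n_active Named counts of non-zero coefficients per tuned neuron.
#' @param effect_size Magnitude of planted non-zero coefficients (log-rate
#'   units per feature count); a single value or a named per-family vector.
#' @param latencies Named per-family response-bump centres (s, relative to
#'   word onset; must lie in the planning window).
#' @param bump_sd Gaussian bump s.d. (s).
#' @param bump_share Fraction of a tuned neuron's window spikes placed in
#'   the latency bump (the rest are uniform across the window).
#' @param baseline_log_rate,baseline_sd Normal distribution of per-neuron
#'   baseline log spikes-per-window.
#' @param listen_fraction Fraction of units phonetically tuned during
#'   listening (among perception-block participants).
#' @param overlap_fraction Fraction of units tuned in both conditions.
#' @param shared_epoch_fraction Fraction of tuned units whose production
#'   coefficients equal their planning coefficients (the rest redraw).
#' @param overlap_planning_fraction Fraction of words whose 500 ms planning
#'   window overlaps the preceding word's articulation; inter-word gaps are
#'   log-normal with `iwi_sdlog` and a median calibrated to reach this.
#' @param iwi_sdlog Log-scale s.d. of the inter-word gap distribution.
#' @param morph_prob Per-word probability of carrying a bound morpheme.
#' @param syllable_count_probs Probabilities of a word having 1..k syllables.
#' @param spatial_gradient Non-negative tilt of tuned units toward caudal
#'   recording sites (0 = uniform).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 5,
                       units_range = c(16, 115),
                       words_per_participant = 850,
                       listen_words_per_participant = 0,
                       n_listen_participants = 3,
                       planning_window = c(-0.5, 0),
                       production_window = c(0, 0.5),
                       perception_window = c(0, 0.5),
                       tuned_fractions = c(place = 0.206, manner = 0.206,
                                           syllable = 0.25, morpheme = 0.114),
                       family_assignment = c("independent", "disjoint"),
                       n_active = c(place = 2, manner = 2, syllable = 1,
                                    morpheme = 1),
                       effect_size = 0.8,
                       latencies = c(morpheme = -0.4, place = -0.2,
                                     manner = -0.2, syllable = -0.08),
                       bump_sd = 0.05,
                       bump_share = 0.7,
                       baseline_log_rate = log(1.5),
                       baseline_sd = 0.3,
                       listen_fraction = 0.293,
                       overlap_fraction = 0.079,
                       shared_epoch_fraction = 0.7,
                       overlap_planning_fraction = 0.1,
                       iwi_sdlog = 0.5,
                       morph_prob = 0.3,
                       syllable_count_probs = c(0.45, 0.3, 0.15, 0.1),
                       spatial_gradient = 0,
                       seed = NULL) {
  assert_that(!is.null(seed), "sim_config() requires an explicit seed")
  family_assignment <- match.arg(family_assignment)
  fr <- c(tuned_fractions, listen_fraction, overlap_fraction,
          shared_epoch_fraction, overlap_planning_fraction, morph_prob)
  assert_that(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  assert_that(n_participants >= 1 && words_per_participant >= 1 &&
                all(units_range >= 1), "all counts must be >= 1")
  assert_that(diff(planning_window) > 0 && diff(production_window) > 0,
              "analysis windows must have positive length")
  assert_that(all(latencies >= planning_window[1] & latencies < planning_window[2]),
              "latencies must lie within the planning window")

  structure(
    list(
      n_participants = n_participants, units_range = units_range,
      words_per_participant = words_per_participant,
      listen_words_per_participant = listen_words_per_participant,
      n_listen_participants = min(n_listen_participants, n_participants),
      planning_window = planning_window,
      production_window = production_window,
      perception_window = perception_window,
      tuned_fractions = tuned_fractions,
      family_assignment = family_assignment,
      n_active = n_active, effect_size = effect_size,
      latencies = latencies, bump_sd = bump_sd, bump_share = bump_share,
      baseline_log_rate = baseline_log_rate, baseline_sd = baseline_sd,
      listen_fraction = listen_fraction, overlap_fraction = overlap_fraction,
      shared_epoch_fraction = shared_epoch_fraction,
      overlap_planning_fraction = overlap_planning_fraction,
      iwi_sdlog = iwi_sdlog, morph_prob = morph_prob,
      syllable_count_probs = syllable_count_probs,
      spatial_gradient = spatial_gradient,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default syllable pool of the synthetic lexicon
#'
#' A weighted pool of ARPAbet syllables covering all eight consonant places,
#' both vowel heights and all six manners, including order-contrast pairs
#' (D-AA-G vs G-AA-D) that exercise the syllable-control categories.
#'
#' @return Tibble with list-column `syllable` and numeric `weight`.
#' @export
default_phonotactics <- function() {
  syl <- list(
    c("D", "AA", "G"), c("G", "AA", "D"), c("K", "AE", "T"),
    c("L", "AY", "K"), c("B", "AY", "K"), c("S", "T", "AA", "P"),
    c("M", "AH", "N"), c("T", "IH", "NG"), c("R", "IY"), c("P", "EY"),
    c("N", "OW"), c("HH", "EH", "D"), c("F", "UH", "T"),
    c("SH", "AH", "N"), c("W", "EH", "L"), c("K", "AH"), c("D", "IY"),
    c("B", "AO", "L"), c("CH", "EH", "K"), c("Y", "UW"), c("Z", "IH", "P"),
    c("TH", "IH", "NG"), c("V", "AE", "N"), c("JH", "AH", "M")
  )
  w <- c(8, 5, 8, 7, 5, 5, 7, 7, 6, 5, 5, 4, 4, 5, 4, 5, 5, 5, 3, 4, 3, 3, 3, 3)
  tibble(syllable = syl, weight = w / sum(w))
}

#' Generate a synthetic lexicon of word forms
#'
#' Words are built by concatenating 1-4 syllables drawn (with replacement)
#' from a weighted syllable pool; syllable spans follow directly from the
#' construction. Bound-morphology flags are Bernoulli draws; a flagged word
#' is a prefix or suffix carrier with equal probability.
#'
#' @param n_words Number of words (0 gives an empty list).
#' @param phonotactics Tibble with list-column `syllable` and `weight`
#'   (defaults to [default_phonotactics()]).
#' @param morph_prob Probability a word carries a bound morpheme.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param syllable_count_probs Probabilities for 1..k syllables per word.
#' @return List of `word_form`s.
#' @export
generate_lexicon <- function(n_words, phonotactics = default_phonotactics(),
                             morph_prob = 0.3, seed = 1,
                             syllable_count_probs = c(0.45, 0.3, 0.15, 0.1)) {
  assert_that(n_words >= 0, "n_words must be >= 0")
  assert_that(morph_prob >= 0 && morph_prob <= 1, "invalid morph_prob")
  assert_that(abs(sum(syllable_count_probs) - 1) < 1e-8 &&
                all(syllable_count_probs >= 0),
              "syllable_count_probs must be a probability vector")
  if (n_words == 0) return(list())

  with_seed(seed, {
    lapply(seq_len(n_words), function(i) {
      k <- sample.int(length(syllable_count_probs), 1,
                      prob = syllable_count_probs)
      idx <- sample.int(nrow(phonotactics), k, replace = TRUE,
                        prob = phonotactics$weight)
      syls <- phonotactics$syllable[idx]
      phon <- unlist(syls)
      lens <- lengths(syls)
      ends <- cumsum(lens)
      spans <- lapply(seq_along(lens), function(j) {
        (ends[j] - lens[j] + 1L):ends[j]
      })
      has_morph <- runif(1) < morph_prob
      pre <- has_morph && runif(1) < 0.5
      parse_word(
        orthography = paste0(tolower(paste(phon, collapse = "")), "_", i),
        phonemes = phon, syllables = spans,
        has_prefix = pre, has_suffix = has_morph && !pre
      )
    })
  })
}

#' Plant per-neuron ground truth
#'
#' Draws, for `n_neurons` units, the baseline log-rates, sparse per-family
#' coefficient vectors for planning (and production, redrawn for neurons
#' with distinct epoch coding), condition membership with the configured
#' speak/listen overlap, and the response latency of each neuron's dominant
#' family.
#'
#' @param n_neurons Total units across participants.
#' @param config A [sim_config()].
#' @param fs A [feature_space()] giving the family dimensionalities.
#' @return Object of class `ground_truth` with a `neurons` tibble and
#'   per-family coefficient matrices in `beta` (planning), `beta_production`
#'   and `beta_listen`.
#' @export
generate_ground_truth <- function(n_neurons, config, fs) {
  stopifnot(inherits(config, "sim_config"), inherits(fs, "feature_space"))
  fams <- intersect(names(config$tuned_fractions), feature_families(fs))

  with_seed(derive_seed(config$seed, "ground_truth"), {
    beta0 <- rnorm(n_neurons, config$baseline_log_rate, config$baseline_sd)

    tuned <- matrix(FALSE, n_neurons, length(fams),
                    dimnames = list(NULL, fams))
    if (config$family_assignment == "independent") {
      for (f in fams) {
        k <- round(config$tuned_fractions[[f]] * n_neurons)
        if (k > 0) tuned[sample.int(n_neurons, k), f] <- TRUE
      }
    } else {
      pool <- sample.int(n_neurons)
      used <- 0
      for (f in fams) {
        k <- round(config$tuned_fractions[[f]] * n_neurons)
        if (used + k > n_neurons) k <- n_neurons - used
        if (k > 0) tuned[pool[(used + 1):(used + k)], f] <- TRUE
        used <- used + k
      }
    }

    # effect size may be one magnitude or a named per-family vector
    fam_effect <- function(f) {
      es <- config$effect_size
      if (!is.null(names(es))) (es[[f]] %||% mean(es)) else es
    }
    draw_beta <- function(f) {
      d <- ncol(fs$design[[f]])
      B <- matrix(0, n_neurons, d,
                  dimnames = list(NULL, colnames(fs$design[[f]])))
      for (i in which(tuned[, f])) {
        na <- min(config$n_active[[f]] %||% 1, d)
        pos <- sample.int(d, na)
        B[i, pos] <- fam_effect(f) * sample(c(-1, 1), na, replace = TRUE)
      }
      B
    }
    beta <- lapply(stats::setNames(fams, fams), draw_beta)

    coupling <- ifelse(runif(n_neurons) < config$shared_epoch_fraction,
                       "shared", "distinct")
    beta_prod <- lapply(stats::setNames(fams, fams), function(f) {
      B <- beta[[f]]
      redraw <- draw_beta(f)
      dist <- coupling == "distinct"
      B[dist, ] <- redraw[dist, ]
      B
    })

    # speak/listen condition membership with controlled overlap
    speak_tuned <- which(rowSums(tuned) > 0)
    n_listen <- round(config$listen_fraction * n_neurons)
    n_both <- min(round(config$overlap_fraction * n_neurons),
                  n_listen, length(speak_tuned))
    both <- if (n_both > 0) sample_vec(speak_tuned, n_both) else integer(0)
    rest_pool <- setdiff(seq_len(n_neurons), speak_tuned)
    n_only <- min(n_listen - n_both, length(rest_pool))
    listen_only <- if (n_only > 0) sample_vec(rest_pool, n_only) else integer(0)
    listen_set <- c(both, listen_only)

    beta_listen <- lapply(stats::setNames(fams, fams), function(f) {
      d <- ncol(fs$design[[f]])
      B <- matrix(0, n_neurons, d,
                  dimnames = list(NULL, colnames(fs$design[[f]])))
      if (f == "place") {
        for (i in listen_set) {
          na <- min(config$n_active[[f]] %||% 1, d)
          pos <- sample.int(d, na)
          B[i, pos] <- fam_effect(f) * sample(c(-1, 1), na, replace = TRUE)
        }
      }
      B
    })

    condition <- rep("none", n_neurons)
    condition[speak_tuned] <- "speak"
    condition[listen_only] <- "listen"
    condition[both] <- "both"

    # latency of the dominant family (largest planted coefficient mass)
    latency <- rep(NA_real_, n_neurons)
    for (i in seq_len(n_neurons)) {
      mass <- vapply(fams, function(f) sum(abs(beta[[f]][i, ])), numeric(1))
      if (any(mass > 0)) {
        dom <- fams[which.max(mass)]
        latency[i] <- config$latencies[[dom]] %||% mean(config$planning_window)
      }
    }

    structure(
      list(
        neurons = tibble(
          neuron = seq_len(n_neurons), beta0 = beta0,
          condition = condition, epoch_coupling = coupling,
          latency = latency
        ),
        tuned = tuned, beta = beta, beta_production = beta_prod,
        beta_listen = beta_listen, families = fams
      ),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$neurons), "neurons; tuned per family:",
      paste(sprintf("%s=%d", colnames(x$tuned), colSums(x$tuned)),
            collapse = ", "), "\n")
  invisible(x)
}

# truncated-normal sampler via rejection with uniform fallback
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  for (tries in 1:20) {
    need <- n - length(out)
    if (need <= 0) break
    x <- rnorm(need, mean, sd)
    out <- c(out, x[x >= lo & x < hi])
  }
  if (length(out) < n) out <- c(out, runif(n - length(out), lo, hi))
  out[seq_len(n)]
}

#' Simulate a multi-participant recording session
#'
#' The generative twin of the encoding model: for every word and unit the
#' spike count in each 500 ms analysis window is Poisson with log-rate
#' `beta0 + sum_f beta_f . x_f(word)`; the drawn count is then laid out in
#' time as a mixture of a uniform component and a Gaussian bump centred at
#' the unit's dominant-family latency, so the window count is conserved
#' exactly. Background spiking at the baseline rate fills the time between
#' analysis windows. Inter-word gaps are log-normal, calibrated so the
#' configured fraction of planning windows overlaps the preceding word.
#'
#' @param lexicon List of `word_form`s words are drawn from.
#' @param gt A [generate_ground_truth()] result.
#' @param config The [sim_config()].
#' @param fs The [feature_space()] the ground truth was generated against.
#' @return A `session_bundle`: list with tibbles `words` (one row per
#'   produced/heard word), `spikes` (unit_id, time_s) and `units`, plus the
#'   ground truth, feature space and config.
#' @export
simulate_session <- function(lexicon, gt, config, fs) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  n_neurons <- nrow(gt$neurons)

  with_seed(derive_seed(config$seed, "session"), {
    # partition neurons over participants
    n_units_p <- sample_vec(config$units_range[1]:config$units_range[2],
                            config$n_participants, replace = TRUE)
    # rescale to the available neuron count
    while (sum(n_units_p) > n_neurons) {
      i <- which.max(n_units_p)
      n_units_p[i] <- n_units_p[i] - 1L
    }
    if (sum(n_units_p) < n_neurons) {
      n_units_p[1] <- n_units_p[1] + (n_neurons - sum(n_units_p))
    }
    owner <- rep(seq_len(config$n_participants), n_units_p)

    words_rows <- list()
    spike_rows <- list()
    unit_rows <- list()
    wid <- 0L

    plan_w <- config$planning_window
    prod_w <- config$production_window
    perc_w <- config$perception_window
    win_len <- diff(plan_w)

    # gap calibrated so P(gap < |planning|) = overlap_planning_fraction
    # (clamped away from 0/1 where the log-normal quantile degenerates)
    ov <- min(max(config$overlap_planning_fraction, 1e-4), 0.9)
    meanlog <- log(win_len) - qnorm(ov) * config$iwi_sdlog

    for (p in seq_len(config$n_participants)) {
      units <- which(owner == p)
      unit_ids <- sprintf("p%d_u%03d", p, seq_along(units))

      n_speak <- config$words_per_participant
      n_listen <- if (p <= config$n_listen_participants) {
        config$listen_words_per_participant
      } else 0L
      n_w <- n_speak + n_listen

      lex_idx <- sample.int(length(lexicon), n_w, replace = TRUE)
      wf <- lexicon[lex_idx]
      dur <- 0.06 * vapply(wf, `[[`, integer(1), "n_phonemes") +
        rlnorm(n_w, log(0.12), 0.3)
      gaps <- rlnorm(n_w, meanlog, config$iwi_sdlog)
      onset <- 1 + cumsum(c(0, dur[-n_w])) + cumsum(gaps)
      offset <- onset + dur
      condition <- rep(c("speak", "listen"), c(n_speak, n_listen))

      X <- lapply(gt$families, function(f) fs$design[[f]][lex_idx, , drop = FALSE])
      names(X) <- gt$families

      pw <- tibble(
        word_id = sprintf("w%06d", wid + seq_len(n_w)),
        participant = p,
        orthography = vapply(wf, `[[`, character(1), "orthography"),
        onset_s = onset, offset_s = offset,
        phonemes = lapply(wf, `[[`, "phonemes"),
        syllables = lapply(wf, `[[`, "syllables"),
        has_prefix = vapply(wf, `[[`, logical(1), "has_prefix"),
        has_suffix = vapply(wf, `[[`, logical(1), "has_suffix"),
        n_phonemes = vapply(wf, `[[`, integer(1), "n_phonemes"),
        condition = condition,
        lexicon_index = lex_idx
      )
      wid <- wid + n_w
      words_rows[[p]] <- pw

      speak_i <- which(condition == "speak")
      listen_i <- which(condition == "listen")

      for (u in seq_along(units)) {
        g <- units[u]
        lin <- function(B) {
          rowSums(vapply(gt$families, function(f) {
            X[[f]] %*% B[[f]][g, ]
          }, numeric(n_w)))
        }
        eta_plan <- gt$neurons$beta0[g] + lin(gt$beta)
        eta_prod <- gt$neurons$beta0[g] + lin(gt$beta_production)
        eta_perc <- gt$neurons$beta0[g] + lin(gt$beta_listen)
        if (max(eta_plan, eta_prod, eta_perc) > 10) {
          abort(sprintf(
            "simulated log-rate overflow (max %.2f > 10) for unit %s; reduce effect sizes",
            max(eta_plan, eta_prod, eta_perc), unit_ids[u]),
            class = "phonopop_rate_overflow")
        }

        lat <- gt$neurons$latency[g]
        place_spikes <- function(n_spk, a, b, center) {
          if (n_spk == 0) return(numeric(0))
          if (is.na(center)) return(runif(n_spk, a, b))
          n_bump <- rbinom(1, n_spk, config$bump_share)
          c(rtrunc_norm(n_bump, center, config$bump_sd, a, b),
            runif(n_spk - n_bump, a, b))
        }

        times <- vector("list", 3)
        if (length(speak_i) > 0) {
          cnt_plan <- rpois(length(speak_i), exp(eta_plan[speak_i]))
          cnt_prod <- rpois(length(speak_i), exp(eta_prod[speak_i]))
          times[[1]] <- unlist(lapply(seq_along(speak_i), function(j) {
            on <- onset[speak_i[j]]
            c(place_spikes(cnt_plan[j], on + plan_w[1], on + plan_w[2], on + lat),
              place_spikes(cnt_prod[j], on + prod_w[1], on + prod_w[2],
                           on + mean(prod_w)))
          }))
        }
        if (length(listen_i) > 0) {
          cnt_perc <- rpois(length(listen_i), exp(eta_perc[listen_i]))
          times[[2]] <- unlist(lapply(seq_along(listen_i), function(j) {
            on <- onset[listen_i[j]]
            place_spikes(cnt_perc[j], on + perc_w[1], on + perc_w[2],
                         on + mean(perc_w))
          }))
        }

        # background spikes at the baseline rate, thinned out of all windows
        t_end <- max(offset) + 1
        bg_rate <- exp(gt$neurons$beta0[g]) / win_len
        n_bg <- rpois(1, bg_rate * t_end)
        bg <- runif(n_bg, 0, t_end)
        in_any_window <- rep(FALSE, length(bg))
        for (j in seq_len(n_w)) {
          on <- onset[j]
          lo <- on + (if (condition[j] == "speak") plan_w[1] else perc_w[1])
          hi <- on + (if (condition[j] == "speak") prod_w[2] else perc_w[2])
          in_any_window <- in_any_window | (bg >= lo & bg < hi)
        }
        times[[3]] <- bg[!in_any_window]

        tt <- sort(unlist(times))
        if (length(tt) > 0) {
          spike_rows[[length(spike_rows) + 1L]] <-
            tibble(unit_id = unit_ids[u], time_s = tt)
        }

        unit_rows[[length(unit_rows) + 1L]] <- tibble(
          unit_id = unit_ids[u], participant = p, neuron = g,
          n_spikes = length(tt), t_end = t_end
        )
      }
    }

    words <- bind_rows(words_rows)
    spikes <- bind_rows(spike_rows) %>% arrange(.data$unit_id, .data$time_s)
    units <- bind_rows(unit_rows)

    # unit geometry: depth uniform over the probe; rostro-caudal position
    # optionally tilted so tuned units sit more caudally
    any_tuned <- rowSums(gt$tuned) > 0
    g <- config$spatial_gradient
    rc <- runif(nrow(units), 0, 10)
    if (g > 0) {
      tuned_u <- any_tuned[units$neuron]
      rc[tuned_u] <- 10 * runif(sum(tuned_u))^(1 / (1 + g))
      rc[!tuned_u] <- 10 * runif(sum(!tuned_u))^(1 + g)
    }
    units <- units %>%
      mutate(
        depth_um = runif(n(), 0, 3000),
        depth_bin = as.integer(cut(.data$depth_um, c(0, 1000, 2000, 3000),
                                   labels = FALSE, include.lowest = TRUE)),
        rostrocaudal_mm = rc,
        mean_rate_hz = .data$n_spikes / .data$t_end
      ) %>%
      select("unit_id", "participant", "neuron", "depth_um", "depth_bin",
             "rostrocaudal_mm", "mean_rate_hz")

    structure(
      list(words = words, spikes = spikes, units = units,
           ground_truth = gt, feature_space = fs, config = config),
      class = "session_bundle"
    )
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>",
      nrow(x$units), "units,",
      nrow(x$words), "words,",
      nrow(x$spikes), "spikes;",
      length(unique(x$words$participant)), "participants\n")
  invisible(x)
}

#' Simulate one small session in a single call
#'
#' Convenience wrapper chaining [generate_lexicon()], [feature_space()],
#' [generate_ground_truth()] and [simulate_session()].
#'
#' @param config A [sim_config()].
#' @param n_lexicon Distinct word forms in the vocabulary.
#' @param n_neurons Total units (defaults to the sum of per-participant
#'   draws implied by the config).
#' @param ... Passed to [feature_space()].
#' @return A `session_bundle`.
#' @export
simulate_bundle <- function(config, n_lexicon = 250, n_neurons = NULL, ...) {
  lex <- generate_lexicon(n_lexicon, morph_prob = config$morph_prob,
                          seed = derive_seed(config$seed, "lexicon"),
                          syllable_count_probs = config$syllable_count_probs)
  fs <- feature_space(lex, ...)
  if (is.null(n_neurons)) {
    n_neurons <- with_seed(derive_seed(config$seed, "ground_truth"), {
      sum(sample_vec(config$units_range[1]:config$units_range[2],
                     config$n_participants, replace = TRUE))
    })
  }
  gt <- generate_ground_truth(n_neurons, config, fs)
  simulate_session(lex, gt, config, fs)
}

#' Synthetic spectral features for a word
#'
#' Draws per-phoneme band powers from place-group-specific log-normal
#' spectral profiles so that spectral regressors correlate with phoneme
#' identity. Each place group has a dominant band; separation controls how
#' far apart (in log-power units) dominant and off bands sit.
#'
#' @param word A `word_form`.
#' @param profiles Matrix groups x bands of mean log-powers, as produced by
#'   [acoustic_profiles()].
#' @param sd Log-scale s.d. of the draw (0 gives deterministic features).
#' @param seed Optional seed.
#' @param place_inv Place inventory.
#' @return List with `band_power` (matrix phonemes x 10), `word_band_power`
#'   (mean over phonemes) and `rms`.
#' @export
simulate_acoustic_features <- function(word, profiles = acoustic_profiles(),
                                       sd = 0.3, seed = NULL,
                                       place_inv = phoneme_inventory("place")) {
  stopifnot(inherits(word, "word_form"))
  grp <- map_symbols(word$phonemes, place_inv)
  with_seed(seed, {
    bp <- t(vapply(grp, function(g) {
      exp(profiles[g, ] + rnorm(ncol(profiles), 0, sd))
    }, numeric(ncol(profiles))))
    rms <- exp(rnorm(1, 0, 0.2))
    list(band_power = bp, word_band_power = colMeans(bp), rms = rms)
  })
}

#' Place-group spectral profiles
#'
#' Mean log-power per band for each place group; group `i` dominates band
#' `1 + (i - 1) %% n_bands`.
#'
#' @param separation Log-power gap between a group's dominant band and the
#'   others.
#' @param n_bands Number of bands.
#' @param place_inv Place inventory.
#' @return Matrix groups x bands with group rownames.
#' @export
acoustic_profiles <- function(separation = 2, n_bands = 10,
                              place_inv = phoneme_inventory("place")) {
  gs <- place_inv$groups
  prof <- matrix(0, length(gs), n_bands, dimnames = list(gs, NULL))
  for (i in seq_along(gs)) {
    prof[i, 1 + (i - 1) %% n_bands] <- separation
  }
  prof
}
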