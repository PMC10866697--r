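#' Smoothed instantaneous firing rates aligned to word onset
#'
#' Bins one unit's spikes into `bin`-wide windows around each word onset
#' and convolves with a Gaussian kernel (s.d. `kernel_sd`), giving an
#' estimated instantaneous rate in spikes/s per time bin per trial. The
#' kernel is built on a grid padded by four standard deviations on each
#' side so a spike's full kernel mass is retained before cropping to the
#' requested window.
#'
#' @param spike_times Sorted spike times of one unit (s).
#' @param onsets Word-onset times (s), one per trial.
#' @param window Analysis window `c(a, b)` relative to onset (s).
#' @param bin Bin width (default 5 ms).
#' @param kernel_sd Gaussian kernel s.d. (default 25 ms; the trajectory
#'   analyses use 50 ms).
#' @return Matrix trials x time bins of non-negative rates, with the bin
#'   centres as attribute `time`.
#' @export
instantaneous_rates <- function(spike_times, onsets, window = c(-0.5, 0),
                                bin = 0.005, kernel_sd = 0.025) {
  assert_that(bin > 0 && kernel_sd > 0, "bin and kernel_sd must be positive")
  pad <- ceiling(4 * kernel_sd / bin)
  edges <- seq(window[1] - pad * bin, window[2] + pad * bin, by = bin)
  n_bins <- length(edges) - 1
  centers <- edges[-1] - bin / 2

  kern_idx <- (-pad):pad
  kern <- exp(-(kern_idx * bin)^2 / (2 * kernel_sd^2))
  kern <- kern / sum(kern)

  keep <- centers >= window[1] & centers < window[2]
  out <- matrix(0, length(onsets), sum(keep))
  for (i in seq_along(onsets)) {
    rel <- spike_times - onsets[i]
    rel <- rel[rel >= edges[1] & rel < edges[n_bins + 1]]
    if (length(rel) > 0) {
      cnt <- tabulate(findInterval(rel, edges), nbins = n_bins)
      sm <- as.numeric(stats::filter(cnt, kern, sides = 2))
      sm[is.na(sm)] <- 0
      out[i, ] <- sm[keep] / bin
    }
  }
  attr(out, "time") <- centers[keep]
  attr(out, "bin") <- bin
  attr(out, "kernel_sd") <- kernel_sd
  out
}

#' Rate tensor for a session
#'
#' Stacks [instantaneous_rates()] over the units of a count matrix into a
#' trials x units x time array sharing the count matrix's word and unit
#' filters.
#'
#' @param session A `session_bundle`.
#' @param cm A `count_matrix` (defines words/units retained).
#' @param window,bin,kernel_sd See [instantaneous_rates()].
#' @return 3-d array (trials, units, time) with a `time` attribute.
#' @export
rate_tensor <- function(session, cm, window = c(-0.5, 0), bin = 0.005,
                        kernel_sd = 0.025) {
  spk <- split(session$spikes$time_s, session$spikes$unit_id)
  onsets <- cm$words$onset_s
  first <- instantaneous_rates(spk[[cm$unit_ids[1]]] %||% numeric(0), onsets,
                               window, bin, kernel_sd)
  arr <- array(0, c(length(onsets), length(cm$unit_ids), ncol(first)))
  arr[, 1, ] <- first
  for (u in seq_along(cm$unit_ids)[-1]) {
    arr[, u, ] <- instantaneous_rates(spk[[cm$unit_ids[u]]] %||% numeric(0),
                                      onsets, window, bin, kernel_sd)
  }
  attr(arr, "time") <- attr(first, "time")
  arr
}

#' Time-resolved decoding and peak-time statistics
#'
#' Trains feature decoders at successive time points during word planning
#' and locates, per split and per feature family, the time of peak mean
#' AUC. Reported per family: the median peak time with a bootstrapped
#' standard error of the median, plus pairwise two-sided permutation tests
#' on differences in median peak time and a Kruskal-Wallis test across
#' families. Split assignments are shared across time points so each
#' split's AUC(t) trace is coherent.
#'
#' @param rates Trials x units x time array (see [rate_tensor()]).
#' @param labels Named list, one element per feature family: logical
#'   matrix trials x dimensions.
#' @param cfg A [decoder_config()].
#' @param eval_stride Evaluate every `eval_stride`-th time bin.
#' @param n_boot Bootstrap resamples for the s.e. of the median.
#' @param n_perm Label-exchange permutations for the pairwise tests.
#' @return Object of class `temporal_decoding`: `auc` (tibble family x
#'   split x time), `peaks` (per family x split), `summary`, `pairwise`,
#'   `kruskal_p`.
#' @export
temporal_decoding <- function(rates, labels, cfg = decoder_config(),
                              eval_stride = 1, n_boot = 1000, n_perm = 2000) {
  time <- attr(rates, "time")
  t_idx <- seq(1, length(time), by = eval_stride)
  n <- dim(rates)[1]
  fams <- names(labels)
  assert_that(length(fams) >= 1, "no feature families")

  with_seed(cfg$seed, {
    splits <- lapply(seq_len(cfg$n_splits), function(s) {
      tr <- sample.int(n, round(cfg$train_fraction * n))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })

    auc_rows <- list()
    for (f in fams) {
      lab <- as.matrix(labels[[f]]) > 0
      dims_ok <- which(colSums(lab) * cfg$train_fraction >= cfg$min_positives &
                         colSums(!lab) * cfg$train_fraction >= 2)
      if (length(dims_ok) == 0) next
      for (ti in t_idx) {
        x_t <- rates[, , ti]
        if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = n)
        gamma <- cfg$gamma %||% (1 / ncol(x_t))
        for (s in seq_along(splits)) {
          tr <- splits[[s]]$train; te <- splits[[s]]$test
          dim_auc <- vapply(dims_ok, function(d) {
            y <- lab[, d]
            if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
              return(NA_real_)
            }
            cost <- select_cost(x_t[tr, , drop = FALSE], y[tr], cfg, gamma)
            sc <- svm_scores(x_t[tr, , drop = FALSE], y[tr],
                             x_t[te, , drop = FALSE], gamma, cost)
            score_auc(sc, y[te])
          }, numeric(1))
          auc_rows[[length(auc_rows) + 1L]] <- tibble(
            family = f, split = s, time = time[ti],
            auc = mean(dim_auc, na.rm = TRUE)
          )
        }
      }
    }
    auc_tbl <- bind_rows(auc_rows)

    # per-split peak time: earliest argmax; flat traces flagged ambiguous
    peaks <- auc_tbl %>%
      group_by(.data$family, .data$split) %>%
      summarise(
        peak_time = .data$time[which.max(.data$auc)],
        ambiguous = max(.data$auc) - min(.data$auc) < 1e-12,
        .groups = "drop"
      )

    boot_se_median <- function(x) {
      if (length(x) < 2) return(NA_real_)
      sd(vapply(seq_len(n_boot), function(i) {
        median(sample_vec(x, length(x), replace = TRUE))
      }, numeric(1)))
    }
    summary_tbl <- peaks %>%
      group_by(.data$family) %>%
      summarise(median_peak = median(.data$peak_time),
                se_median = boot_se_median(.data$peak_time),
                n_ambiguous = sum(.data$ambiguous), .groups = "drop")

    perm_median_test <- function(a, b) {
      obs <- abs(median(a) - median(b))
      pool <- c(a, b); na <- length(a)
      hits <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pool), na)
        abs(median(pool[idx]) - median(pool[-idx])) >= obs - 1e-15
      }, logical(1))
      (sum(hits) + 1) / (n_perm + 1)
    }
    pw <- if (length(fams) >= 2) {
      combs <- utils::combn(fams, 2)
      bind_rows(lapply(seq_len(ncol(combs)), function(j) {
        a <- peaks$peak_time[peaks$family == combs[1, j]]
        b <- peaks$peak_time[peaks$family == combs[2, j]]
        tibble(family_a = combs[1, j], family_b = combs[2, j],
               p.value = perm_median_test(a, b))
      }))
    } else tibble()

    kr <- if (length(fams) >= 2) {
      kruskal.test(peaks$peak_time, factor(peaks$family))$p.value
    } else NA_real_

    structure(
      list(auc = auc_tbl, peaks = peaks, summary = summary_tbl,
           pairwise = pw, kruskal_p = kr, time = time[t_idx]),
      class = "temporal_decoding"
    )
  })
}

#' @export
print.temporal_decoding <- function(x, ...) {
  cat("<temporal_decoding>", length(unique(x$auc$family)), "families;",
      length(x$time), "time points\n")
  print(x$summary)
  invisible(x)
}
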