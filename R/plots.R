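#' Plot a Hamming-distance tuning curve
#'
#' Mean z-scored rate (±s.e.m.) per Hamming distance bin.
#'
#' @param object A `tuning_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tuning_curve
#' @export
autoplot.tuning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$mean_z)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_z - .data$sem,
                                      ymax = .data$mean_z + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Hamming distance from preferred composition",
      y = "z-scored firing rate",
      subtitle = if (!is.na(attr(object, "rho"))) {
        sprintf("Spearman rho = %.2f", attr(object, "rho"))
      } else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-split decoding scores
#'
#' Distribution of the per-split mean ROC-AUC, with the per-dimension
#' spread behind it.
#'
#' @param object A `decoder_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decoder_result
#' @export
autoplot.decoder_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$dimension, y = .data$auc)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ROC-AUC") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved decoding traces
#'
#' Mean AUC over splits as a function of time for each feature family.
#'
#' @param object A `temporal_decoding`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot temporal_decoding
#' @export
autoplot.temporal_decoding <- function(object, ...) {
  avg <- object$auc %>%
    group_by(.data$family, .data$time) %>%
    summarise(auc = mean(.data$auc), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time, y = .data$auc,
                                    colour = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = object$summary,
      ggplot2::aes(xintercept = .data$median_peak, colour = .data$family),
      linetype = 3
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "time from word onset (s)", y = "mean ROC-AUC") +
    ggplot2::theme_minimal()
}

#' Plot an alignment-index null distribution
#'
#' Histogram of the Monte-Carlo null with the observed index marked.
#'
#' @param object An `alignment_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alignment_null
#' @export
autoplot.alignment_null <- function(object, ...) {
  df <- tibble(alignment = object$null)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$alignment)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::labs(x = "alignment index (chance)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(object$observed)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed,
                                 colour = "red")
  }
  p
}
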