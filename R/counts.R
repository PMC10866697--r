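#' Spike-count matrix for an analysis window
#'
#' Counts each unit's spikes in a half-open window `[a, b)` relative to
#' every word's onset. Two filters from the recording protocol are applied
#' and logged: units with session-mean firing rate below `min_rate_hz`
#' (default 0.1 Hz) are dropped, and -- for the planning/production windows
#' -- words whose 500 ms planning period overlaps the preceding word's
#' articulation are excluded so preceding-word activity cannot leak in.
#'
#' @param session A `session_bundle`.
#' @param window `"planning"` (`[-0.5, 0)`), `"production"` (`[0, 0.5)`),
#'   `"perception"` (the configured listening window on listen-condition
#'   words) or a numeric `c(a, b)` in seconds.
#' @param exclude_overlap Apply the overlapping-planning-period exclusion.
#' @param min_rate_hz Minimum session-mean firing rate for a unit.
#' @return Object of class `count_matrix`: integer matrix `counts`
#'   (units x words) plus `word_ids`, `unit_ids`, the window, and an
#'   `excluded` log tibble with one row per dropped word/unit and a reason.
#' @export
assemble_counts <- function(session, window = "planning",
                            exclude_overlap = TRUE, min_rate_hz = 0.1) {
  stopifnot(inherits(session, "session_bundle"))
  assert_that(nrow(session$words) > 0 && nrow(session$units) > 0,
              "empty session", class = "phonopop_empty_session")

  cfg <- session$config
  if (is.character(window)) {
    tag <- match.arg(window, c("planning", "production", "perception"))
    win <- switch(tag,
      planning = cfg$planning_window %||% c(-0.5, 0),
      production = cfg$production_window %||% c(0, 0.5),
      perception = cfg$perception_window %||% c(0, 0.5)
    )
  } else {
    tag <- "custom"
    win <- as.numeric(window)
    assert_that(length(win) == 2 && diff(win) > 0, "bad window")
  }

  words <- session$words
  words <- if (tag == "perception") {
    filter(words, .data$condition == "listen")
  } else {
    filter(words, .data$condition == "speak")
  }
  assert_that(nrow(words) > 0, "no words in this condition",
              class = "phonopop_empty_session")

  excluded <- tibble(id = character(0), kind = character(0),
                     reason = character(0))

  if (exclude_overlap && tag != "perception") {
    plan_w <- cfg$planning_window %||% c(-0.5, 0)
    words <- words %>%
      group_by(.data$participant) %>%
      arrange(.data$onset_s, .by_group = TRUE) %>%
      mutate(prev_offset = dplyr::lag(.data$offset_s, default = -Inf),
             overlaps = .data$onset_s + plan_w[1] < .data$prev_offset) %>%
      ungroup()
    excluded <- bind_rows(excluded, tibble(
      id = words$word_id[words$overlaps], kind = "word",
      reason = "planning_overlap"
    ))
    words <- filter(words, !.data$overlaps) %>%
      select(-"prev_offset", -"overlaps")
  }

  units <- session$units
  low <- units$mean_rate_hz < min_rate_hz
  excluded <- bind_rows(excluded, tibble(
    id = units$unit_id[low], kind = "unit", reason = "rate_below_min"
  ))
  units <- units[!low, , drop = FALSE]
  assert_that(nrow(units) > 0, "no units pass the rate filter",
              class = "phonopop_empty_session")

  lo <- words$onset_s + win[1]
  hi <- words$onset_s + win[2]
  spk <- split(session$spikes$time_s, session$spikes$unit_id)
  counts <- t(vapply(units$unit_id, function(u) {
    s <- spk[[u]]
    if (is.null(s)) return(integer(nrow(words)))
    findInterval(hi, s, left.open = TRUE) -
      findInterval(lo, s, left.open = TRUE)
  }, integer(nrow(words))))
  dimnames(counts) <- list(units$unit_id, words$word_id)

  structure(
    list(counts = counts, window = tag, window_s = win,
         word_ids = words$word_id, unit_ids = units$unit_id,
         words = words, units = units, excluded = excluded),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", x$window,
      sprintf("[%g, %g) s:", x$window_s[1], x$window_s[2]),
      nrow(x$counts), "units x", ncol(x$counts), "words;",
      nrow(x$excluded), "exclusions\n")
  invisible(x)
}

# Per-unit z-scored counts across included words (rows: units).
zscore_counts <- function(cm) {
  m <- cm$counts
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- NA_real_
  sweep(sweep(m, 1, mu), 1, s, `/`)
}
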