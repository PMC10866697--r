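#' Write a session bundle to delimited files
#'
#' Serializes a session as three inspectable CSV files (`words.csv`,
#' `spikes.csv`, `units.csv`) plus, when present, a `ground_truth.json`
#' sidecar. Phoneme sequences are pipe-separated symbols; syllable spans
#' are 1-based inclusive ranges like `"1-3|4-6"`; all times are seconds.
#'
#' @param session A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  words <- session$words %>%
    mutate(
      phonemes = vapply(.data$phonemes, paste, character(1), collapse = "|"),
      syllable_spans = vapply(.data$syllables, function(sp) {
        paste(vapply(sp, function(s) paste0(s[1], "-", s[length(s)]),
                     character(1)), collapse = "|")
      }, character(1))
    ) %>%
    select("word_id", "participant", "orthography", "onset_s", "offset_s",
           "phonemes", "syllable_spans", prefix = "has_prefix",
           suffix = "has_suffix", "condition")
  readr::write_csv(words, file.path(dir, "words.csv"))
  readr::write_csv(session$spikes, file.path(dir, "spikes.csv"))
  readr::write_csv(session$units %>% select(-dplyr::any_of("neuron")),
                   file.path(dir, "units.csv"))

  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    jsonlite::write_json(
      list(neurons = gt$neurons, families = gt$families,
           tuned = as.data.frame(gt$tuned),
           beta = lapply(gt$beta, as.data.frame),
           beta_production = lapply(gt$beta_production, as.data.frame)),
      file.path(dir, "ground_truth.json"),
      dataframe = "columns", digits = I(17), na = "null"
    )
  }
  invisible(dir)
}

#' Load a session bundle from delimited files
#'
#' Reads and validates `words.csv`, `spikes.csv` and `units.csv` written by
#' [write_session()] (or produced by an external annotation pipeline with
#' the same columns). Validation failures name the offending rows or ids.
#'
#' @param dir Directory containing the three files.
#' @param planning_window,production_window,perception_window Analysis
#'   windows attached to the bundle.
#' @return A `session_bundle` (without ground truth or feature space; the
#'   feature space is rebuilt from the word forms on demand).
#' @export
load_session <- function(dir, planning_window = c(-0.5, 0),
                         production_window = c(0, 0.5),
                         perception_window = c(0, 0.5)) {
  need <- file.path(dir, c("words.csv", "spikes.csv", "units.csv"))
  missing <- need[!file.exists(need)]
  assert_that(length(missing) == 0,
              paste0("missing session file(s): ",
                     paste(basename(missing), collapse = ", ")),
              class = "phonopop_missing_file")

  words <- readr::read_csv(need[1], show_col_types = FALSE, progress = FALSE)
  spikes <- readr::read_csv(need[2], show_col_types = FALSE, progress = FALSE)
  units <- readr::read_csv(need[3], show_col_types = FALSE, progress = FALSE)

  req_w <- c("word_id", "participant", "orthography", "onset_s", "offset_s",
             "phonemes", "syllable_spans", "prefix", "suffix", "condition")
  req_s <- c("unit_id", "time_s")
  req_u <- c("unit_id", "participant", "mean_rate_hz")
  check_cols <- function(df, req, file) {
    miss <- setdiff(req, names(df))
    assert_that(length(miss) == 0,
                paste0(file, " is missing column(s): ",
                       paste(miss, collapse = ", ")),
                class = "phonopop_missing_column")
  }
  check_cols(words, req_w, "words.csv")
  check_cols(spikes, req_s, "spikes.csv")
  check_cols(units, req_u, "units.csv")

  orphan <- setdiff(unique(spikes$unit_id), units$unit_id)
  assert_that(length(orphan) == 0,
              paste0("spikes.csv references unknown unit_id(s): ",
                     paste(orphan, collapse = ", ")),
              class = "phonopop_orphan_unit")

  unsorted <- spikes %>%
    group_by(.data$unit_id) %>%
    summarise(bad = any(diff(.data$time_s) < 0), .groups = "drop") %>%
    filter(.data$bad)
  assert_that(nrow(unsorted) == 0,
              paste0("unsorted spike times for unit(s): ",
                     paste(unsorted$unit_id, collapse = ", ")),
              class = "phonopop_unsorted_spikes")
  assert_that(all(spikes$time_s >= 0), "negative spike times",
              class = "phonopop_unsorted_spikes")

  parse_spans <- function(s) {
    lapply(strsplit(s, "|", fixed = TRUE)[[1]], function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      ab[1]:ab[2]
    })
  }
  words <- words %>%
    arrange(.data$participant, .data$onset_s) %>%
    mutate(
      phonemes = strsplit(.data$phonemes, "|", fixed = TRUE),
      syllables = lapply(.data$syllable_spans, parse_spans),
      has_prefix = as.logical(.data$prefix),
      has_suffix = as.logical(.data$suffix),
      n_phonemes = lengths(.data$phonemes)
    ) %>%
    select(-"syllable_spans", -"prefix", -"suffix")

  cfg <- list(planning_window = planning_window,
              production_window = production_window,
              perception_window = perception_window)
  structure(
    list(words = words, spikes = arrange(spikes, .data$unit_id, .data$time_s),
         units = units, ground_truth = NULL, feature_space = NULL,
         config = cfg),
    class = "session_bundle"
  )
}

#' Read interval tiers from a Praat TextGrid
#'
#' Minimal long-format TextGrid reader for the `"words"` and `"phones"`
#' interval tiers produced by forced alignment.
#'
#' @param path TextGrid file path.
#' @param tiers Tier names to keep.
#' @return Tibble with `tier`, `xmin`, `xmax`, `text` (empty intervals
#'   dropped).
#' @export
read_textgrid <- function(path, tiers = c("words", "phones")) {
  lines <- readLines(path, warn = FALSE)
  get_num <- function(s) as.numeric(sub(".*=\\s*", "", s))
  get_str <- function(s) gsub("\"", "", sub(".*=\\s*", "", s))

  out <- list()
  tier_name <- NA_character_
  xmin <- NA_real_; xmax <- NA_real_
  for (ln in trimws(lines)) {
    if (grepl("^name\\s*=", ln)) tier_name <- get_str(ln)
    else if (grepl("^xmin\\s*=", ln)) xmin <- get_num(ln)
    else if (grepl("^xmax\\s*=", ln)) xmax <- get_num(ln)
    else if (grepl("^text\\s*=", ln)) {
      txt <- get_str(ln)
      if (!is.na(tier_name) && tier_name %in% tiers && nzchar(txt)) {
        out[[length(out) + 1L]] <- tibble(
          tier = tier_name, xmin = xmin, xmax = xmax, text = txt
        )
      }
    }
  }
  bind_rows(out)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Drives simulate -> selectivity -> decoding -> subspace and writes every
#' stage's artefacts (CSV/JSON) plus a run report to `out_dir`. Fully
#' reproducible: the same configuration and seed give byte-identical JSON
#' outputs (floats serialized at 17 significant digits).
#'
#' @param config Named list: `seed`, `sim` (arguments to [sim_config()]
#'   beyond the seed), `families`, `decoder` (arguments to
#'   [decoder_config()]), `n_lexicon`, `subspace_k`, `null_reps`, and
#'   `stages` (subset of `"simulate"`, `"selectivity"`, `"decode"`,
#'   `"subspace"`).
#' @param out_dir Output directory.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "selectivity", "decode",
                                 "subspace")
  report <- list(package_version = as.character(utils::packageVersion("phonopop")),
                 seed = config$seed, stages = stages)
  t0 <- Sys.time()

  sim_args <- modifyList(
    list(n_participants = 2, units_range = c(12, 18),
         words_per_participant = 150, seed = config$seed),
    config$sim %||% list()
  )
  scfg <- do.call(sim_config, sim_args)
  session <- simulate_bundle(scfg, n_lexicon = config$n_lexicon %||% 150)
  if ("simulate" %in% stages) {
    write_session(session, file.path(out_dir, "session"))
    report$simulate <- list(n_words = nrow(session$words),
                            n_units = nrow(session$units),
                            n_spikes = nrow(session$spikes))
  }

  families <- config$families %||% c("place", "syllable", "morpheme")

  if ("selectivity" %in% stages) {
    sel <- neuron_selectivity(session, families = families)
    cm <- attr(sel, "counts")
    readr::write_csv(
      sel %>% select(-"wald", -"preferred"),
      file.path(out_dir, "selectivity.csv")
    )
    report$selectivity <- list(
      n_units_in = nrow(session$units),
      n_units_included = length(cm$unit_ids),
      n_units_excluded = sum(cm$excluded$kind == "unit"),
      n_words_in = sum(session$words$condition == "speak"),
      n_words_included = length(cm$word_ids),
      n_words_excluded = sum(cm$excluded$kind == "word"),
      tuned_per_family = as.list(
        sel %>% group_by(.data$family) %>%
          summarise(n_tuned = sum(.data$tuned), .groups = "drop") %>%
          tidyr::pivot_wider(names_from = "family", values_from = "n_tuned")
      )
    )
  }

  if ("decode" %in% stages) {
    dec_args <- modifyList(
      list(n_splits = 10, cost_grid = 1,
           seed = derive_seed(config$seed, "decoder")),
      config$decoder %||% list()
    )
    dcfg <- do.call(decoder_config, dec_args)
    fam <- families[1]
    trials <- decoding_trials(session, family = fam)
    P <- build_pseudopopulation(trials,
                                seed = derive_seed(config$seed, "pseudopop"))
    res <- train_feature_decoders(P, dcfg, keep_models = FALSE)
    null <- shuffle_null(P, dcfg, n_reps = config$null_reps %||% 20,
                         seed = derive_seed(config$seed, "null"))
    jsonlite::write_json(
      list(family = fam, mean_auc = res$summary$mean_auc,
           sd_auc = res$summary$sd_auc, split_mean = res$split_mean,
           skipped = res$skipped, null_mean = mean(null$null_auc),
           null_q975 = unname(quantile(null$null_auc, 0.975)),
           null_auc = null$null_auc),
      file.path(out_dir, "decoding.json"),
      digits = I(17), auto_unbox = TRUE
    )
    report$decode <- list(family = fam, n_trials = nrow(P$rates),
                          n_neurons = ncol(P$rates),
                          mean_auc = res$summary$mean_auc)
  }

  if ("subspace" %in% stages) {
    cmp <- compare_subspaces(session, k = config$subspace_k %||% 5,
                             n_reps = config$null_reps %||% 1000,
                             seed = derive_seed(config$seed, "subspace"))
    jsonlite::write_json(
      list(
        alignment_planning_in_production = cmp$alignment_planning_in_production,
        alignment_production_in_planning = cmp$alignment_production_in_planning,
        null_mean = mean(cmp$null$null),
        null_q025 = unname(quantile(cmp$null$null, 0.025)),
        null_q975 = unname(quantile(cmp$null$null, 0.975)),
        chordal = cmp$chordal,
        chordal_normalized = cmp$chordal_normalized,
        var_explained = cmp$var_explained
      ),
      file.path(out_dir, "subspace.json"), digits = I(17), auto_unbox = TRUE
    )
    report$subspace <- list(k = cmp$k, n_units = length(cmp$units))
  }

  report$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  # wall clock excluded from the determinism-checked artefacts by design
  jsonlite::write_json(report[setdiff(names(report), "wall_clock_s")],
                       file.path(out_dir, "report.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(report)
}
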