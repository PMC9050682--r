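#' Configuration for a full simulation-and-analysis run
#'
#' Collects every tunable of the pipeline. All stage seeds are derived
#' deterministically from `seed` and the stage name, so a config reproduces
#' a run bit-for-bit.
#'
#' @param seed Master seed.
#' @param n_participants Number of simulated participants.
#' @param n_sequences Sequences per participant (multiple of 32).
#' @param n_channels EEG channels.
#' @param fm_overrides Named list of [make_forward_model()] overrides
#'   (e.g. `list(amplitude = 0)` for a noise-only run).
#' @param between_subject_sd SD of the per-participant evoked amplitude.
#' @param lambda LDA shrinkage parameter.
#' @param isi_filters ISI splits to decode (`"all"` only, or all three).
#' @param prior_scale,prior_interval Cauchy prior scale and excluded
#'   interval for the Bayes factors.
#' @param n_boot Bootstrap samples for confidence intervals.
#' @param bf_threshold Evidence threshold for onset detection.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_participants = 20L, n_sequences = 64L,
                       n_channels = 64L, fm_overrides = list(),
                       between_subject_sd = 0.25, lambda = 0.01,
                       isi_filters = c("all", "constant", "varied"),
                       prior_scale = 0.707, prior_interval = 0.5,
                       n_boot = 10000L, bf_threshold = 10) {
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         n_sequences = as.integer(n_sequences), n_channels = as.integer(n_channels),
         fm_overrides = fm_overrides, between_subject_sd = between_subject_sd,
         lambda = lambda, isi_filters = isi_filters,
         prior_scale = prior_scale, prior_interval = prior_interval,
         n_boot = as.integer(n_boot), bf_threshold = bf_threshold),
    class = "run_config"
  )
}

# Internal: simulate, preprocess and decode one participant; the raw
# recordings are discarded as soon as the epochs are decoded.
decode_participant <- function(config, i) {
  pid <- sprintf("sim%02d", i)
  design <- generate_session(pid, derive_seed(config$seed, "design", i),
                             config$n_sequences)
  fm <- do.call(
    participant_forward_model,
    c(list(base_seed = config$seed, i = i, n_channels = config$n_channels,
           between_subject_sd = config$between_subject_sd),
      config$fm_overrides)
  )
  epochs <- withr::with_seed(derive_seed(config$seed, "noise", i), {
    sets <- lapply(split(design, design$sequence_id), function(seq_des) {
      preprocess_recording(simulate_recording(seq_des, fm))
    })
    bind_epoch_sets(sets)
  })
  run_all_conditions(epochs, isi_filters = config$isi_filters,
                     lambda = config$lambda)
}

#' Run the full pipeline: design, simulation, preprocessing, decoding,
#' group inference
#'
#' Simulates `n_participants` sessions, decodes every condition, and runs
#' the group-level Bayes factor timecourses and onset detection for all
#' contrasts. Participants are processed one at a time so memory stays
#' bounded. If `out_dir` is given, writes `curves.csv` (per-participant
#' decoding), `bf_timecourses.csv`, `onsets.json` and `config.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param contrasts Contrasts passed to [bf_timecourse()].
#' @param ci Attach bootstrap confidence intervals to the group curves.
#' @return Invisibly, a list with `curves` (per-participant tibble), `bf`
#'   (group tibble over contrasts), `onsets` (named list, ms or NA), and
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         contrasts = c("cued_vs_chance", "uncued_vs_chance",
                                       "attention_effect", "expectation_effect",
                                       "attention_effect_constant",
                                       "attention_effect_varied", "interaction"),
                         ci = FALSE) {
  if (!all(c("constant", "varied") %in% config$isi_filters)) {
    contrasts <- setdiff(contrasts, c("expectation_effect", "interaction",
                                      "attention_effect_constant",
                                      "attention_effect_varied"))
  }
  curves <- purrr::map(seq_len(config$n_participants),
                       function(i) decode_participant(config, i)) %>%
    bind_rows()
  if (config$n_participants < 3) {
    # group-level t statistics are fragile at n = 2 (accuracies are
    # quantised and can coincide); skip inference for miniature runs
    contrasts <- character(0)
  }
  bf <- purrr::map(contrasts, function(ct) {
    prior <- prior_spec(config$prior_scale, config$prior_interval,
                        if (ct == "interaction") "two_sided" else "positive_only")
    bf_timecourse(curves, ct, prior = prior, ci = ci, n_boot = config$n_boot,
                  ci_seed = derive_seed(config$seed, "bootstrap"))
  }) %>% bind_rows()
  onsets <- if (length(contrasts) == 0) {
    list()
  } else {
    purrr::map(split(bf, bf$contrast)[unique(bf$contrast)],
               onset_time, threshold = config$bf_threshold)
  }
  result <- list(curves = curves, bf = bf, onsets = onsets, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(curves, file.path(out_dir, "curves.csv"))
    readr::write_csv(bf, file.path(out_dir, "bf_timecourses.csv"))
    jsonlite::write_json(onsets, file.path(out_dir, "onsets.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

#' Build small self-contained fixtures for tests and examples
#'
#' `"tiny"` runs 2 participants x 4 sequences at 16 channels (seconds);
#' `"small"` runs 10 participants x 16 sequences at 32 channels (minutes).
#' Both use the default ground-truth attention effect.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Master seed.
#' @param out_dir Optional directory for the CSV/JSON outputs.
#' @return The [run_pipeline()] result list.
#' @export
make_fixtures <- function(size = c("tiny", "small"), seed = 1L, out_dir = NULL) {
  size <- match.arg(size)
  config <- switch(size,
    tiny = run_config(seed = seed, n_participants = 2L, n_sequences = 4L,
                      n_channels = 16L, isi_filters = "all", n_boot = 500L),
    small = run_config(seed = seed, n_participants = 10L, n_sequences = 16L,
                       n_channels = 32L, n_boot = 2000L)
  )
  run_pipeline(config, out_dir = out_dir)
}
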