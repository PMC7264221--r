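#' Run the full trace-level analysis for one culture window
#'
#' Chains the trace stages end to end: baseline
#' correction/normalization ([process_traces()]), feature extraction
#' and boosted classification (optional), peeling spike inference
#' ([infer_spikes()]), and the culture summary
#' ([summarize_experiment()]).
#'
#' @param raw_traces A raw-stage [trace_tbl()] (e.g. from
#'   [extract_traces()] or [render_traces()]).
#' @param transient The [calcium_transient()] kernel.
#' @param window Name for the analysis window (e.g. `"basal"`).
#' @param training_labels Optional [manual_labels()] table; when given
#'   (or when `classifier` is supplied) only traces classified
#'   neuronal reach the spike-inference stage.
#' @param classifier Optional pre-trained [train_classifier()] model.
#' @param culture_id Identifier for the summary row.
#' @param ... Passed to [peel_trace()] (e.g. `threshold_pct`).
#' @return A list: `summary` (one-row [summarize_experiment()] table),
#'   `spikes`, `labels` (predicted, or `NULL` when unclassified),
#'   `classifier`, `normalized` (the processed trace table).
#' @examples
#' cfg <- sim_config(n_neurons = 4, duration_s = 120, seed = 5)
#' raw <- render_traces(simulate_spike_trains(cfg, "basal"), cfg)
#' res <- run_culture_pipeline(raw, cfg$transient, culture_id = 1)
#' res$summary
#' @export
run_culture_pipeline <- function(raw_traces, transient = calcium_transient(),
                                 window = "full", training_labels = NULL,
                                 classifier = NULL, culture_id = NA_integer_,
                                 ...) {
  norm <- process_traces(raw_traces)
  labels <- NULL
  keep <- norm
  if (!is.null(training_labels) || !is.null(classifier)) {
    feats <- trace_features(norm)
    if (is.null(classifier)) {
      classifier <- train_classifier(feats, training_labels)
    }
    labels <- classify_traces(classifier, feats)
    keep <- norm[norm$roi_id %in%
                   labels$roi_id[labels$class == "neuronal"], ]
    class(keep) <- class(norm)
  }
  f <- raw_traces$frame_rate_hz[1]
  dur <- length(raw_traces$values[[1]]) / f
  spikes <- infer_spikes(keep, transient,
                         windows = tibble(window = window, start_s = 0,
                                          end_s = dur), ...)
  list(
    summary = summarize_experiment(spikes, dur, culture_id = culture_id),
    spikes = spikes, labels = labels, classifier = classifier,
    normalized = norm
  )
}

#' Culture-level summaries for a simulated recruitment experiment
#'
#' Simulates the design, summarizes every culture, and keeps each
#' culture's assigned treatment window, yielding the table of
#' independent culture-level observations the two-factor ANOVA runs on
#' (treatment between cultures, as in a 10/10/5/5 layout).
#'
#' @param design A [recruitment_design()]-style tibble (must carry a
#'   `treatment` column of `"basal"`/`"fourap"`).
#' @param config Base [sim_config()]; `config$seed` is the master seed.
#' @return An `experiment_summary` tibble with one row per culture.
#' @export
run_recruitment_experiment <- function(design = recruitment_design(),
                                       config = sim_config()) {
  if (!"treatment" %in% names(design)) {
    abort("`design` must assign each condition a `treatment` window.")
  }
  xs <- simulate_experiment_set(design, config)
  summarize_experiment_set(xs, config$duration_s) |>
    dplyr::inner_join(
      dplyr::select(xs, "culture_id", treatment = "treatment"),
      by = "culture_id"
    ) |>
    dplyr::filter(.data$window == .data$treatment) |>
    dplyr::select(-"window")
}

#' Replicate the recruitment experiment and score interaction power
#'
#' Repeats [run_recruitment_experiment()] under independent derived
#' seeds and runs the genotype x treatment ANOVA on the chosen
#' response in each replicate, reporting the interaction p value per
#' replicate and the fraction detected at `alpha`.
#'
#' @param n_reps Number of replicate experiments.
#' @param design,config As in [run_recruitment_experiment()].
#' @param response Summary column to test (default `"n_active"`).
#' @param alpha Detection level (default 0.05).
#' @param seed Master seed for the replicate series.
#' @return A tibble `rep, p_interaction`, with attribute
#'   `"detection_rate"`.
#' @export
recruitment_power <- function(n_reps = 100, design = recruitment_design(),
                              config = sim_config(), response = "n_active",
                              alpha = 0.05, seed = 1L) {
  ps <- purrr::map_dbl(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 101L, r)
    class(cfg) <- "sim_config"
    smry <- run_recruitment_experiment(design, cfg)
    av <- two_way_anova(smry, response, "genotype", "treatment")
    av$effects$p.value[av$effects$effect == "interaction"]
  })
  out <- tibble(rep = seq_len(n_reps), p_interaction = ps)
  attr(out, "detection_rate") <- mean(ps < alpha)
  out
}
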