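#' Render non-neuronal artifact traces
#'
#' Three artifact classes used to train and test the trace classifier:
#' `"flat"` (baseline with low-variance noise and no transients),
#' `"slow_wave"` (large astrocyte-like slow oscillation), and `"step"`
#' (an abrupt sustained baseline discontinuity).
#'
#' @param class One of `"flat"`, `"slow_wave"`, `"step"`.
#' @param config A [sim_config()] (supplies duration, frame rate,
#'   baseline, noise scale).
#' @param seed Seed for this trace's draws.
#' @return Numeric raw-fluorescence trace.
#' @export
render_artifact_trace <- function(class = c("flat", "slow_wave", "step"),
                                  config, seed = 1L) {
  class <- match.arg(class)
  f <- config$frame_rate_hz
  n <- round(config$duration_s * f)
  tt <- (seq_len(n) - 1) / f
  B <- config$baseline_level
  withr::with_seed(seed, {
    base <- switch(class,
      flat = rep(B, n),
      slow_wave = B * (1 + 0.04 * sin(2 * pi * tt / runif(1, 20, 60) +
                                        runif(1, 0, 2 * pi))),
      step = B * (1 + 0.03 * sign(rnorm(1)) * (tt >= runif(1, 0.2, 0.8) *
                                                 config$duration_s))
    )
    noise_scale <- if (class == "flat") 0.5 else 1
    base + rnorm(n, 0, noise_scale * config$noise_sd / 100 * B)
  })
}

#' Simulate a multi-culture experiment set
#'
#' One independently seeded culture per row of the design: each culture
#' gets basal and 4-AP spike trains (via [simulate_spike_trains()]) and,
#' optionally, rendered raw traces including a configurable fraction of
#' labelled non-neuronal artifact traces appended after the neuronal
#' ROIs.  Per-culture seeds are derived deterministically from the
#' master seed, so the whole set is reproducible bit-for-bit.
#'
#' @param design A tibble with one row per condition cell, columns
#'   `genotype` (any factor-like label), `n_cultures`, and optionally
#'   any [sim_config()] argument to override per condition (e.g.
#'   `recruitment_prob`).
#' @param config Base [sim_config()]; its `seed` is the master seed.
#' @param render If `TRUE`, also render raw trace tables (slow for
#'   large designs); otherwise only spike trains and labels.
#' @return A tibble, one row per culture: `culture_id`, `genotype`,
#'   `seed`, `config` (list), `spikes_basal`, `spikes_fourap`
#'   (list of [simulate_spike_trains()] outputs), `labels` (ground
#'   truth trace classes) and, when rendered, `traces_basal`,
#'   `traces_fourap`.
#' @examples
#' design <- tibble::tibble(genotype = c("wt", "ko"), n_cultures = c(2, 2),
#'                          recruitment_prob = c(0.4, 0))
#' xs <- simulate_experiment_set(design, sim_config(n_neurons = 20))
#' @export
simulate_experiment_set <- function(design, config = sim_config(),
                                    render = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("genotype", "n_cultures") %in% names(design))) {
    abort("`design` needs columns `genotype` and `n_cultures`.")
  }
  if (any(design$n_cultures < 1)) abort("need >= 1 culture per condition.")
  override_cols <- intersect(names(design),
                             setdiff(names(config), c("transient", "seed")))
  carry_cols <- setdiff(names(design), c("n_cultures", override_cols))
  rows <- list()
  cid <- 0L
  for (i in seq_len(nrow(design))) {
    cfg_i <- config
    for (col in override_cols) cfg_i[[col]] <- design[[col]][i]
    for (j in seq_len(design$n_cultures[i])) {
      cid <- cid + 1L
      cfg_ij <- cfg_i
      cfg_ij$seed <- derive_seed(config$seed, 17L, cid)
      class(cfg_ij) <- "sim_config"
      sb <- simulate_spike_trains(cfg_ij, "basal")
      sf <- simulate_spike_trains(cfg_ij, "fourap")
      n_art <- round(cfg_ij$artifact_fraction * cfg_ij$n_neurons /
                       max(1e-12, 1 - cfg_ij$artifact_fraction))
      art_classes <- rep(c("flat", "slow_wave", "step"), length.out = n_art)
      labels <- tibble(
        roi_id = seq_len(cfg_ij$n_neurons + n_art),
        class = c(rep("neuronal", cfg_ij$n_neurons),
                  rep("non_neuronal", n_art)),
        artifact_class = c(rep(NA_character_, cfg_ij$n_neurons), art_classes)
      )
      row <- tibble(culture_id = cid, seed = cfg_ij$seed)
      for (col in carry_cols) row[[col]] <- design[[col]][i]
      row$config <- list(cfg_ij)
      row$spikes_basal <- list(sb)
      row$spikes_fourap <- list(sf)
      row$labels <- list(labels)
      if (render) {
        render_window <- function(spk, w_idx) {
          tb <- render_traces(spk, cfg_ij)
          if (n_art > 0) {
            art <- purrr::imap(art_classes, function(cl, a) {
              render_artifact_trace(cl, cfg_ij,
                                    derive_seed(cfg_ij$seed, 23L, w_idx, a))
            })
            tb <- trace_tbl(labels$roi_id,
                            c(tb$values, art), cfg_ij$frame_rate_hz, "raw")
          }
          tb
        }
        row$traces_basal <- list(render_window(sb, 1L))
        row$traces_fourap <- list(render_window(sf, 2L))
      }
      rows[[cid]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' The 10/10/5/5 basal vs 4-AP recruitment design
#'
#' Convenience builder for the reference experiment layout: two
#' astrocyte-genotype conditions, with recruitment of silent neurons
#' under 4-AP present in one (`recruitment_prob = 0.4`) and absent in
#' the other (`0`); 10 cultures per genotype assigned to the basal
#' window and 5 per genotype to the 4-AP window, giving 30 independent
#' culture-level observations.
#'
#' @param n_cultures Cultures per cell, order: wt-basal, ko-basal,
#'   wt-fourap, ko-fourap.
#' @param recruitment_wt,recruitment_ko Recruitment probabilities by
#'   genotype condition.
#' @return A design tibble for [simulate_experiment_set()] with columns
#'   `genotype`, `treatment` (the window each culture contributes),
#'   `n_cultures`, `recruitment_prob`.
#' @export
recruitment_design <- function(n_cultures = c(10, 10, 5, 5),
                               recruitment_wt = 0.4, recruitment_ko = 0) {
  tibble(
    genotype = c("wt", "ko", "wt", "ko"),
    treatment = c("basal", "basal", "fourap", "fourap"),
    n_cultures = n_cultures,
    recruitment_prob = c(recruitment_wt, recruitment_ko,
                         recruitment_wt, recruitment_ko)
  )
}
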