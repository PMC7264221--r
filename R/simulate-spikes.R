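#' Simulate per-neuron Poisson spike trains for one recording window
#'
#' Active neurons fire as homogeneous Poisson processes at
#' `basal_rate_hz`; in the `"fourap"` window their rate is multiplied by
#' `fourap_rate_multiplier` and each basally silent neuron is
#' independently recruited (becomes active at the boosted rate) with
#' probability `recruitment_prob`.  The silent pool is the last
#' `round(silent_fraction * n_neurons)` neurons, so ground-truth
#' membership is reproducible from the config alone.
#'
#' @param config A [sim_config()].
#' @param window `"basal"` or `"fourap"`.
#'
#' @return A tibble with one row per neuron: `roi_id`, `window`,
#'   `basal_active` (ground-truth basal status), `active_truth` (fires
#'   at a positive rate in this window), `rate_hz` (the generating
#'   rate), and `spikes`, a list-column of sorted spike times in
#'   seconds within `[0, duration_s)`.
#' @examples
#' st <- simulate_spike_trains(sim_config(n_neurons = 10, seed = 7), "basal")
#' st$spikes[[1]]
#' @export
simulate_spike_trains <- function(config, window = c("basal", "fourap")) {
  stopifnot(inherits(config, "sim_config"))
  window <- match.arg(window)
  if (config$duration_s <= 0) abort("invalid config: nonpositive duration.")
  n <- config$n_neurons
  n_silent <- round(config$silent_fraction * n)
  basal_active <- c(rep(TRUE, n - n_silent), rep(FALSE, n_silent))

  w_idx <- match(window, c("basal", "fourap"))
  withr::with_seed(derive_seed(config$seed, w_idx), {
    if (window == "basal") {
      rate <- ifelse(basal_active, config$basal_rate_hz, 0)
    } else {
      recruited <- !basal_active &
        (runif(n) < config$recruitment_prob)
      rate <- ifelse(basal_active | recruited,
                     config$basal_rate_hz * config$fourap_rate_multiplier, 0)
    }
    spikes <- lapply(rate, function(r) {
      k <- rpois(1, r * config$duration_s)
      sort(runif(k, 0, config$duration_s))
    })
  })

  tibble(
    roi_id = seq_len(n),
    window = window,
    basal_active = basal_active,
    active_truth = rate > 0,
    rate_hz = rate,
    spikes = spikes
  )
}
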