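#' Per-neuron firing rate
#'
#' @param n_spikes Spike count(s) in the analysis window.
#' @param window_duration_s Window duration, seconds (> 0).
#' @return Rate(s) in Hz.
#' @examples
#' firing_rate(12, 600)  # 0.02 Hz
#' @export
firing_rate <- function(n_spikes, window_duration_s) {
  if (any(window_duration_s <= 0)) abort("`window_duration_s` must be > 0.")
  n_spikes / window_duration_s
}

#' Count active neurons
#'
#' A neuron is active when at least one spike was detected in the
#' window; the fraction is over all classified neuronal traces.
#'
#' @param n_spikes Integer spike counts, one per classified neuron.
#' @return A tibble `n_active, fraction_active`.
#' @examples
#' count_active(c(0, 2, 0, 1))
#' @export
count_active <- function(n_spikes) {
  if (length(n_spikes) == 0) {
    abort("empty neuron set: fraction of active neurons is undefined.")
  }
  n_act <- sum(n_spikes >= 1)
  tibble(n_active = n_act, fraction_active = n_act / length(n_spikes))
}

#' Global firing rate of a culture
#'
#' Total spikes across all classified neurons per unit time, not
#' divided by the neuron count (set `per_neuron = TRUE` for the
#' per-neuron-normalized variant).
#'
#' @param n_spikes Integer spike counts, one per neuron.
#' @param window_duration_s Window duration, seconds.
#' @param per_neuron Divide by the number of neurons.
#' @return Rate in Hz.
#' @examples
#' global_firing_rate(c(6, 0, 6), 600)  # 0.02 Hz
#' @export
global_firing_rate <- function(n_spikes, window_duration_s,
                               per_neuron = FALSE) {
  if (window_duration_s <= 0) abort("`window_duration_s` must be > 0.")
  r <- sum(n_spikes) / window_duration_s
  if (per_neuron) r / length(n_spikes) else r
}

#' Summarize a culture's spike trains per window
#'
#' Collapses per-neuron spike trains to one row per analysis window —
#' the culture-level "individual experiment" values that are the
#' statistical units of the group comparison: mean per-neuron firing
#' rate, active-neuron count and fraction, and global firing rate.
#'
#' @param spikes A [infer_spikes()]-style tibble (`roi_id`, `window`,
#'   `n_spikes`), restricted to classified neuronal traces, or a
#'   [simulate_spike_trains()] output (its `spikes` list-column is
#'   counted).
#' @param window_duration_s Duration of each window, seconds; either a
#'   single value or a named vector by window.
#' @param culture_id Identifier copied into the output.
#' @return A tibble of class `experiment_summary`, one row per window:
#'   `culture_id, window, n_neurons, mean_firing_rate_hz, n_active,
#'   fraction_active, global_firing_rate_hz`.
#' @examples
#' st <- simulate_spike_trains(sim_config(n_neurons = 20, seed = 1), "basal")
#' summarize_experiment(st, 600, culture_id = 1)
#' @export
summarize_experiment <- function(spikes, window_duration_s,
                                 culture_id = NA_integer_) {
  if (!"n_spikes" %in% names(spikes) && "spikes" %in% names(spikes)) {
    spikes <- dplyr::mutate(spikes, n_spikes = lengths(.data$spikes))
  }
  if (!all(c("roi_id", "window", "n_spikes") %in% names(spikes))) {
    abort("`spikes` needs columns roi_id, window and n_spikes (or spikes).")
  }
  if (nrow(spikes) == 0) abort("no classified neurons to summarize.")
  dur_of <- function(w) {
    if (is.null(names(window_duration_s))) window_duration_s[1]
    else {
      if (!w %in% names(window_duration_s)) {
        abort(sprintf("no duration given for window '%s'.", w))
      }
      window_duration_s[[w]]
    }
  }
  out <- spikes |>
    dplyr::group_by(.data$window) |>
    dplyr::group_modify(function(d, key) {
      dur <- dur_of(key$window)
      act <- count_active(d$n_spikes)
      tibble(
        n_neurons = nrow(d),
        mean_firing_rate_hz = mean(firing_rate(d$n_spikes, dur)),
        n_active = act$n_active,
        fraction_active = act$fraction_active,
        global_firing_rate_hz = global_firing_rate(d$n_spikes, dur)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(culture_id = culture_id, .before = 1)
  class(out) <- c("experiment_summary", class(out))
  out
}

#' Summarize a whole simulated experiment set
#'
#' @param experiment_set Output of [simulate_experiment_set()].
#' @param window_duration_s Window duration, seconds.
#' @return One `experiment_summary` row per culture per window, with
#'   the design columns (`genotype`) carried along.
#' @export
summarize_experiment_set <- function(experiment_set, window_duration_s) {
  out <- purrr::pmap_dfr(
    list(experiment_set$culture_id, experiment_set$genotype,
         experiment_set$spikes_basal, experiment_set$spikes_fourap),
    function(cid, gt, sb, sf) {
      spk <- dplyr::bind_rows(sb, sf)
      summarize_experiment(spk, window_duration_s, culture_id = cid) |>
        dplyr::mutate(genotype = gt, .after = "culture_id")
    }
  )
  class(out) <- c("experiment_summary", class(out))
  out
}
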