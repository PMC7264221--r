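#' Build a trace table
#'
#' The package's canonical in-memory container for fluorescence traces:
#' one row per ROI, with the sample vector in the `values` list-column.
#' `stage` records where each trace sits in the processing chain
#' (`"raw"`, `"smoothed"` or `"normalized"`; normalized traces are in
#' percent \eqn{\Delta F/F}).
#'
#' @param roi_id Integer ROI ids.
#' @param values List of numeric vectors, one per ROI, equal lengths.
#' @param frame_rate_hz Frames per second.
#' @param stage Processing stage of all traces in the table.
#'
#' @return A tibble of class `trace_tbl` with columns `roi_id`,
#'   `frame_rate_hz`, `stage`, `values`.
#' @export
trace_tbl <- function(roi_id, values, frame_rate_hz,
                      stage = c("raw", "smoothed", "normalized")) {
  stage <- match.arg(stage)
  if (length(roi_id) != length(values)) {
    abort("`roi_id` and `values` must have the same length.")
  }
  lens <- lengths(values)
  if (length(lens) > 0 && length(unique(lens)) != 1) {
    abort("all traces must have the same number of frames.")
  }
  out <- tibble(
    roi_id = as.integer(roi_id),
    frame_rate_hz = frame_rate_hz,
    stage = stage,
    values = lapply(values, as.numeric)
  )
  class(out) <- c("trace_tbl", class(out))
  out
}

#' Render a raw fluorescence trace from a spike train
#'
#' Forward model inverted later by the peeling stage: each spike adds
#' one transient-template copy (linear superposition, non-saturating),
#' on top of a slow sinusoidal baseline drift, scaled to raw
#' fluorescence units and corrupted by additive Gaussian noise:
#' \deqn{F(t) = B \left[1 + \frac{d(t)}{100} +
#'   \frac{1}{100}\sum_k A e^{-(t - t_k)/\tau} 1\{t \ge t_k\}\right] +
#'   \varepsilon(t)}
#' with \eqn{B} the baseline level, \eqn{d(t)} the drift in percent and
#' \eqn{\varepsilon \sim N(0, (B \cdot \mathrm{noise\_sd}/100)^2)}.
#'
#' @param spikes Sorted spike times in seconds.
#' @param config A [sim_config()]; supplies the transient, drift, noise
#'   and baseline parameters.
#' @param seed Seed for the noise draw; `NULL` renders noiselessly.
#'
#' @return Numeric vector of `duration_s * frame_rate_hz` raw
#'   fluorescence values.
#' @examples
#' x <- render_trace(c(5, 6), sim_config(noise_sd = 0, drift_amplitude = 0))
#' @export
render_trace <- function(spikes, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.unsorted(spikes)) abort("`spikes` must be sorted.")
  f <- config$frame_rate_hz
  n <- round(config$duration_s * f)
  k <- transient_template(config$transient, n, f)
  clean <- numeric(n)
  for (t_k in spikes) {
    p <- floor(t_k * f) + 1L
    if (p < 1 || p > n) next
    idx <- p:min(n, p + length(k) - 1L)
    clean[idx] <- clean[idx] + k[seq_along(idx)]
  }
  tt <- (seq_len(n) - 1) / f
  drift <- config$drift_amplitude * sin(2 * pi * tt / config$drift_period_s)
  raw <- config$baseline_level * (1 + drift / 100 + clean / 100)
  if (!is.null(seed) && config$noise_sd > 0) {
    raw <- raw + withr::with_seed(
      seed, rnorm(n, 0, config$noise_sd / 100 * config$baseline_level)
    )
  }
  raw
}

#' Render the raw trace table for one window's spike trains
#'
#' @param spike_tbl Output of [simulate_spike_trains()].
#' @param config The same [sim_config()].
#' @return A raw-stage [trace_tbl()] with one row per neuron.
#' @export
render_traces <- function(spike_tbl, config) {
  w_idx <- match(spike_tbl$window[1] %||% "basal", c("basal", "fourap"))
  vals <- purrr::map2(
    spike_tbl$spikes, spike_tbl$roi_id,
    function(s, id) {
      render_trace(s, config, seed = derive_seed(config$seed, 7L, w_idx, id))
    }
  )
  trace_tbl(spike_tbl$roi_id, vals, config$frame_rate_hz, "raw")
}
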