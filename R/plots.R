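#' Plot traces stacked by ROI
#'
#' @param traces A [trace_tbl()].
#' @param offset Vertical offset between traces (default: scaled to the
#'   trace spread).
#' @param spikes Optional [infer_spikes()] table; inferred spikes are
#'   drawn as vertical ticks under each trace.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, offset = NULL, spikes = NULL) {
  stopifnot(inherits(traces, "trace_tbl"))
  f <- traces$frame_rate_hz[1]
  if (is.null(offset)) {
    offset <- 1.2 * max(purrr::map_dbl(traces$values,
                                       ~ diff(range(.x))), na.rm = TRUE)
  }
  rank <- match(traces$roi_id, sort(unique(traces$roi_id)))
  d <- purrr::pmap_dfr(
    list(traces$roi_id, traces$values, rank),
    function(id, v, rk) {
      tibble(roi_id = id, time_s = (seq_along(v) - 1) / f,
             value = v + (rk - 1) * offset)
    }
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value,
                                       group = .data$roi_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s fluorescence (stacked)",
                              traces$stage[1])) +
    ggplot2::theme_minimal()
  if (!is.null(spikes)) {
    rank_s <- match(spikes$roi_id, sort(unique(traces$roi_id)))
    sd_ <- purrr::pmap_dfr(
      list(spikes$roi_id, spikes$spike_times_s, rank_s),
      function(id, ts, rk) {
        tibble(roi_id = id, time_s = ts, y = (rk - 1) * offset - 0.2 * offset)
      }
    )
    if (nrow(sd_) > 0) {
      p <- p + ggplot2::geom_point(
        data = sd_, ggplot2::aes(.data$time_s, .data$y),
        shape = "|", size = 2, inherit.aes = FALSE
      )
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.trace_tbl <- function(object, ...) plot_traces(object, ...)

#' Spike raster across neurons
#'
#' @param spikes An [infer_spikes()]-style table with `spike_times_s`.
#' @return A ggplot object.
#' @export
plot_spike_raster <- function(spikes) {
  d <- purrr::map2_dfr(spikes$roi_id, spikes$spike_times_s,
                       ~ tibble(roi_id = .x, time_s = .y))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, factor(.data$roi_id))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Experiment-summary group plot
#'
#' One point per culture with the group mean bar, split by genotype and
#' treatment window — the standard recruitment read-out layout.
#'
#' @param summaries An `experiment_summary` tibble with `genotype` and
#'   a window/treatment column.
#' @param response Summary column to plot.
#' @param window_col Column distinguishing basal vs 4-AP (default
#'   `"treatment"`, falling back to `"window"`).
#' @return A ggplot object.
#' @export
plot_summary_points <- function(summaries, response = "n_active",
                                window_col = NULL) {
  if (is.null(window_col)) {
    window_col <- if ("treatment" %in% names(summaries)) "treatment"
    else "window"
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data[[window_col]], .data[[response]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$genotype)) +
    ggplot2::labs(x = NULL, y = response) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_summary <- function(object, ...) {
  plot_summary_points(object, ...)
}
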