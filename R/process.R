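#' Smooth a trace with a centered moving average
#'
#' Window must be odd; at the edges the window is truncated to the
#' available samples, so the output has the same length as the input.
#'
#' @param values Numeric trace.
#' @param window_frames Odd window width in frames (default 5, i.e.
#'   0.25 s at 20 frames/s).
#' @return Smoothed numeric trace.
#' @export
smooth_trace <- function(values, window_frames = 5) {
  if (length(window_frames) != 1 || window_frames < 1 ||
      window_frames %% 2 == 0) {
    abort("`window_frames` must be a positive odd integer.")
  }
  n <- length(values)
  h <- (window_frames - 1) / 2
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Pick per-block baseline reference points
#'
#' The trace is cut into consecutive blocks of `block_s` seconds.  In
#' each block the value at the lower `lower_percentile` fluorescence
#' percentile is computed (linear-interpolation convention) and the
#' reference point is the block sample whose value is nearest that
#' percentile (earliest sample on ties), at its own time coordinate.  A
#' trailing partial block keeps its own reference point when it holds at
#' least a quarter of a block's frames; otherwise it is merged into the
#' previous block.
#'
#' @param values Numeric trace (conventionally the smoothed trace).
#' @param frame_rate_hz Frames per second.
#' @param block_s Block length in seconds (default 50).
#' @param lower_percentile Lower-tail fraction (default 0.10, the 10th
#'   percentile).
#' @return A tibble `time_s, value, frame` with one row per block,
#'   times strictly increasing.
#' @export
pick_reference_points <- function(values, frame_rate_hz, block_s = 50,
                                  lower_percentile = 0.10) {
  n <- length(values)
  if (n < 1) abort("empty trace.")
  bpf <- max(1L, round(block_s * frame_rate_hz))
  n_full <- n %/% bpf
  rem <- n - n_full * bpf
  starts <- bpf * (seq_len(max(n_full, 1)) - 1) + 1
  ends <- pmin(starts + bpf - 1, n)
  if (n_full == 0) {
    ends <- n  # trace shorter than one block: single partial block
  } else if (rem > 0) {
    if (rem >= 0.25 * bpf) {
      starts <- c(starts, n_full * bpf + 1)
      ends <- c(ends, n)
    } else {
      ends[n_full] <- n  # merge small remainder into last full block
    }
  }
  purrr::map2_dfr(starts, ends, function(a, b) {
    block <- values[a:b]
    q <- unname(quantile(block, lower_percentile, type = 7))
    i <- which.min(abs(block - q))  # earliest on ties
    tibble(time_s = (a + i - 2) / frame_rate_hz, value = block[i],
           frame = a + i - 1L)
  })
}

#' Fit the slow baseline through reference points
#'
#' A cubic smoothing spline through the per-block reference points,
#' evaluated at every frame time, gives the baseline \eqn{F_0}.  With
#' one point the baseline is constant; with two or three the natural
#' spline degenerates gracefully (linear / low-order).  Beyond the
#' first and last reference times the baseline is held constant.  The
#' default is a pass-through (interpolating) spline: with roughly a
#' dozen reference points per 10-min recording extra smoothing adds
#' little; set `spar` to engage penalised smoothing.
#'
#' @param reference_points Tibble from [pick_reference_points()].
#' @param n_frames Number of frames to evaluate the baseline at.
#' @param frame_rate_hz Frames per second.
#' @param spar Optional `smooth.spline` smoothing parameter in (0, 1];
#'   `NULL` (default) interpolates the reference points.
#' @return An object of class `baseline_model`: a list with
#'   `reference_points` and `baseline_values` (length `n_frames`).
#' @export
fit_baseline <- function(reference_points, n_frames, frame_rate_hz,
                         spar = NULL) {
  rp <- reference_points
  if (nrow(rp) < 1) abort("need at least one reference point.")
  tt <- (seq_len(n_frames) - 1) / frame_rate_hz
  if (nrow(rp) == 1) {
    f0 <- rep(rp$value[1], n_frames)
  } else {
    # constant-value extrapolation outside the reference span
    tc <- pmin(pmax(tt, min(rp$time_s)), max(rp$time_s))
    if (!is.null(spar) && nrow(rp) >= 4) {
      fit <- smooth.spline(rp$time_s, rp$value, spar = spar)
      f0 <- predict(fit, tc)$y
    } else {
      f0 <- splinefun(rp$time_s, rp$value, method = "natural")(tc)
    }
  }
  structure(list(reference_points = rp, baseline_values = f0),
            class = "baseline_model")
}

#' Normalize a raw trace to percent dF/F
#'
#' \deqn{100 \times (F(t) - F_0(t)) / F_0(t)} applied to the original
#' (unsmoothed) trace, with \eqn{F_0} the fitted baseline.
#'
#' @param values Raw numeric trace.
#' @param baseline A [fit_baseline()] model (or a numeric \eqn{F_0}
#'   vector of the same length).
#' @return Normalized trace in percent \eqn{\Delta F/F}.
#' @export
normalize_trace <- function(values, baseline) {
  f0 <- if (inherits(baseline, "baseline_model")) {
    baseline$baseline_values
  } else {
    as.numeric(baseline)
  }
  if (length(f0) != length(values)) {
    abort("baseline and trace lengths differ.")
  }
  bad <- which(f0 <= 0)
  if (length(bad) > 0) {
    abort(sprintf("degenerate baseline: F0 <= 0 at frame %d.", bad[1]))
  }
  100 * (values - f0) / f0
}

#' Smooth, baseline-correct and normalize a trace table
#'
#' The full trace-conditioning chain, per ROI: centered moving-average
#' smoothing; per-50 s-block lower-percentile reference points picked on
#' the smoothed trace; cubic-spline baseline; normalization of the raw
#' trace to percent \eqn{\Delta F/F}.
#'
#' @param traces A raw-stage [trace_tbl()].
#' @param window_frames Smoothing window, odd frames.
#' @param block_s,lower_percentile Reference-point parameters, see
#'   [pick_reference_points()].
#' @param spar Optional spline smoothing parameter, see
#'   [fit_baseline()].
#' @param pick_on Whether reference points are picked on the smoothed
#'   (default) or raw trace.
#' @return A normalized-stage [trace_tbl()] with extra list-columns
#'   `baseline` (\eqn{F_0} per frame) and `reference_points`.
#' @examples
#' cfg <- sim_config(n_neurons = 2, duration_s = 120, seed = 3)
#' raw <- render_traces(simulate_spike_trains(cfg, "basal"), cfg)
#' norm <- process_traces(raw)
#' @export
process_traces <- function(traces, window_frames = 5, block_s = 50,
                           lower_percentile = 0.10, spar = NULL,
                           pick_on = c("smoothed", "raw")) {
  stopifnot(inherits(traces, "trace_tbl"))
  pick_on <- match.arg(pick_on)
  f <- traces$frame_rate_hz[1]
  done <- purrr::map(traces$values, function(x) {
    sm <- smooth_trace(x, window_frames)
    rp <- pick_reference_points(if (pick_on == "smoothed") sm else x,
                                f, block_s, lower_percentile)
    bl <- fit_baseline(rp, length(x), f, spar = spar)
    list(values = normalize_trace(x, bl),
         baseline = bl$baseline_values, reference_points = rp)
  })
  out <- trace_tbl(traces$roi_id, purrr::map(done, "values"), f, "normalized")
  out$baseline <- purrr::map(done, "baseline")
  out$reference_points <- purrr::map(done, "reference_points")
  out
}
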