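#' Peel spikes out of one normalized trace
#'
#' Greedy peeling with matched-filter detection: the residual is
#' correlated with the unit transient template; the global best
#' candidate onset is accepted if its implied event amplitude (the
#' least-squares amplitude of one template at that onset) reaches the
#' detection threshold, one template of fixed amplitude is subtracted
#' there, and the search repeats on the residual.  Superposition is
#' linear, so several spikes may share a frame; there is no refractory
#' constraint.
#'
#' The correlation is recomputed only on the frames a subtraction
#' touches, so peeling a 10-min 20-Hz trace with tens of spikes takes
#' milliseconds.
#'
#' @param values Normalized trace in percent \eqn{\Delta F/F}.
#' @param model A [calcium_transient()] (the kernel used for every
#'   trace).
#' @param frame_rate_hz Frames per second.
#' @param threshold_pct Minimum implied event amplitude to accept a
#'   spike, in percent \eqn{\Delta F/F}.  Default half the template
#'   amplitude; `"mad"` uses a noise-adaptive 3 x MAD of the
#'   first-difference-estimated residual noise instead.
#' @param local_dc Estimate each candidate's amplitude jointly with a
#'   local DC (constant offset) nuisance term over the template
#'   support (default `TRUE`).  This makes detection insensitive to
#'   residual slow-baseline error, which otherwise masquerades as
#'   event amplitude near the ends of the recording; set `FALSE` for
#'   the plain matched filter.
#' @param max_iter Safety cap on peeled events (default 10 events per
#'   second of trace).
#'
#' @return A list: `spike_frames` (sorted, 1-based, possibly with
#'   repeats), `residual` (input minus all subtracted templates),
#'   `n_iter`, and `max_iter_hit`.
#' @examples
#' cfg <- sim_config()
#' k <- transient_template(calcium_transient(), 400, 20)
#' x <- numeric(400); x[100 + seq_along(k) - 1] <- k
#' peel_trace(x, calcium_transient(), 20)$spike_frames  # 100
#' @export
peel_trace <- function(values, model, frame_rate_hz,
                       threshold_pct = model$amplitude_pct / 2,
                       local_dc = TRUE, max_iter = NULL) {
  stopifnot(inherits(model, "calcium_transient"))
  n <- length(values)
  if (n < 2) abort("trace too short to peel.")
  k <- transient_template(model, n, frame_rate_hz)
  L <- length(k)
  if (is.null(max_iter)) max_iter <- ceiling(10 * n / frame_rate_hz)
  if (identical(threshold_pct, "mad")) {
    # robust noise scale from first differences (transient-insensitive)
    threshold_pct <- 3 * stats::mad(diff(values)) / sqrt(2)
  }

  # per-onset template support (truncated at the trace end) and its
  # moments: support length, sum k, sum k^2
  ls <- pmin(L, n - seq_len(n) + 1L)
  csk <- cumsum(k)
  csk2 <- cumsum(k^2)
  sumk <- csk[ls]
  kk <- csk2[ls]
  # least-squares denominator of the amplitude estimate; with a local
  # DC term the template must have variance over its support
  den <- if (local_dc) kk - sumk^2 / ls else kk
  # onsets so close to the end that the (DC-orthogonalized) template
  # retains little energy are unidentifiable: amplitude estimates there
  # are noise divided by a vanishing denominator
  valid <- ls >= 3L & den >= 0.25 * den[1]

  # cc[i] = sum_j resid[i + j - 1] k[j]; sy[i] = sum of resid over the
  # support, needed for the DC-adjusted amplitude
  cs <- c(0, cumsum(values))
  resid <- values
  cc <- convolve(resid, k, type = "open")[L:(L + n - 1L)]
  sy <- cs[seq_len(n) + ls] - cs[seq_len(n)]

  amp_of <- function() {
    a <- if (local_dc) (cc - sy * sumk / ls) / den else cc / den
    a[!valid] <- -Inf
    a
  }

  spikes <- integer(0)
  iters <- 0L
  hit_cap <- FALSE
  repeat {
    amp <- amp_of()
    i <- which.max(amp)
    if (amp[i] < threshold_pct) break
    if (iters >= max_iter) {
      hit_cap <- TRUE
      warn("peeling stopped at max_iter; residual may still contain events.")
      break
    }
    iters <- iters + 1L
    spikes <- c(spikes, i)
    seg <- i:min(n, i + L - 1L)
    resid[seg] <- resid[seg] - model$amplitude_pct * k[seq_along(seg)]
    # only onsets whose support touches the subtraction change
    w1 <- max(1L, i - L + 1L)
    w2 <- min(n, i + L - 1L)
    slice <- resid[w1:min(n, w2 + L - 1L)]
    cc[w1:w2] <- convolve(slice, k, type = "open")[L:(L + (w2 - w1))]
    scs <- c(0, cumsum(slice))
    rel <- seq_len(w2 - w1 + 1L)
    sy[w1:w2] <- scs[pmin(rel + ls[w1:w2], length(scs))] - scs[rel]
  }
  list(spike_frames = sort(spikes), residual = resid,
       n_iter = iters, max_iter_hit = hit_cap)
}

#' Infer spike trains for a table of normalized traces
#'
#' Each trace is peeled once over the whole recording; the inferred
#' spikes are then partitioned into the requested analysis windows by
#' onset time.  Frames outside every window (e.g. a drug-diffusion
#' stabilization gap between the basal and 4-AP windows) are dropped.
#'
#' @param traces A normalized-stage [trace_tbl()] (classified neuronal
#'   traces only).
#' @param model A [calcium_transient()].
#' @param windows A tibble/data.frame `window, start_s, end_s` of
#'   non-overlapping analysis windows; default a single window covering
#'   the whole trace.
#' @param ... Passed to [peel_trace()].
#'
#' @return A tibble of class `spike_tbl` with one row per neuron per
#'   window: `roi_id`, `window`, `n_spikes`, `spike_frames` (0-based
#'   frame indices, list), `spike_times_s` (list), `max_iter_hit`.
#' @examples
#' cfg <- sim_config(n_neurons = 3, duration_s = 120, noise_sd = 0.2, seed = 2)
#' raw <- render_traces(simulate_spike_trains(cfg, "basal"), cfg)
#' infer_spikes(process_traces(raw), cfg$transient)
#' @export
infer_spikes <- function(traces, model, windows = NULL, ...) {
  stopifnot(inherits(traces, "trace_tbl"))
  if (!all(traces$stage == "normalized")) {
    abort("`traces` must be normalized (percent dF/F) before peeling.")
  }
  if (nrow(traces) == 0) {
    out <- tibble(roi_id = integer(), window = character(),
                  n_spikes = integer(), spike_frames = list(),
                  spike_times_s = list(), max_iter_hit = logical())
    class(out) <- c("spike_tbl", class(out))
    return(out)
  }
  f <- traces$frame_rate_hz[1]
  n <- length(traces$values[[1]])
  if (is.null(windows)) {
    windows <- tibble(window = "full", start_s = 0, end_s = n / f)
  }
  windows <- dplyr::arrange(as_tibble(windows), .data$start_s)
  if (nrow(windows) > 1 &&
      any(windows$start_s[-1] < windows$end_s[-nrow(windows)])) {
    abort("analysis windows overlap.")
  }
  if (any(windows$end_s <= windows$start_s)) {
    abort("each window must satisfy start_s < end_s.")
  }

  peeled <- purrr::map(traces$values, peel_trace, model = model,
                       frame_rate_hz = f, ...)
  out <- purrr::map2_dfr(peeled, traces$roi_id, function(p, id) {
    t_s <- (p$spike_frames - 1) / f  # 0-based onset times
    purrr::pmap_dfr(windows, function(window, start_s, end_s) {
      inw <- t_s >= start_s & t_s < end_s
      tibble(
        roi_id = id, window = window, n_spikes = sum(inw),
        spike_frames = list(p$spike_frames[inw] - 1L),
        spike_times_s = list(t_s[inw]),
        max_iter_hit = p$max_iter_hit
      )
    })
  })
  class(out) <- c("spike_tbl", class(out))
  out
}

#' Match inferred spikes to ground truth and score F1
#'
#' Greedy one-to-one matching of inferred to true spike frames within a
#' frame tolerance, then precision/recall/F1.
#'
#' @param inferred,truth Numeric vectors of spike frames (same basis).
#' @param tol_frames Match tolerance in frames (default 1).
#' @return A tibble `n_true, n_inferred, tp, precision, recall, f1`.
#' @export
score_spike_match <- function(inferred, truth, tol_frames = 1) {
  inferred <- sort(inferred)
  truth <- sort(truth)
  used <- rep(FALSE, length(inferred))
  tp <- 0L
  for (t in truth) {
    d <- abs(inferred - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_frames) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- if (length(inferred) > 0) tp / length(inferred) else 1
  rec <- if (length(truth) > 0) tp / length(truth) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble(n_true = length(truth), n_inferred = length(inferred), tp = tp,
         precision = prec, recall = rec, f1 = f1)
}
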