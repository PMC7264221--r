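# shared fixtures and independent oracles

# a small, fast config for unit tests (not the study-condition defaults)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_neurons = 8, duration_s = 120, basal_rate_hz = 0.05,
         noise_sd = 0.2, seed = 11L),
    list(...)
  )
  do.call(sim_config, args)
}

# place unit transient templates at given 1-based onset frames
template_trace <- function(onsets, n_frames, frame_rate_hz = 20,
                           model = calcium_transient()) {
  k <- transient_template(model, n_frames, frame_rate_hz)
  x <- numeric(n_frames)
  for (p in onsets) {
    idx <- p:min(n_frames, p + length(k) - 1L)
    x[idx] <- x[idx] + k[seq_along(idx)]
  }
  x
}

# exhaustive least-squares oracle: best placement of 0, 1 or 2 unit
# templates (by squared residual) over every onset pair of a trace
brute_force_two_spike_oracle <- function(x, frame_rate_hz = 20,
                                         model = calcium_transient()) {
  n <- length(x)
  tm <- vapply(seq_len(n), template_trace, numeric(n),
               n_frames = n, frame_rate_hz = frame_rate_hz, model = model)
  gram <- crossprod(tm)
  cx <- as.vector(crossprod(tm, x))
  xx <- sum(x^2)
  best <- list(rss = xx, spikes = integer(0))  # zero spikes
  rss1 <- xx - 2 * cx + diag(gram)
  i1 <- which.min(rss1)
  if (rss1[i1] < best$rss) best <- list(rss = rss1[i1], spikes = i1)
  rss2 <- outer(rss1, rss1, `+`) - xx + 2 * gram
  i2 <- arrayInd(which.min(rss2), dim(rss2))
  if (min(rss2) < best$rss) {
    best <- list(rss = min(rss2), spikes = sort(as.integer(i2)))
  }
  best
}

# classical two-factor ANOVA by direct summation (balanced designs)
anova_ss_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(y)
  cell_mean <- tapply(y, list(a, b), mean)
  n_cell <- tapply(y, list(a, b), length)
  a_mean <- tapply(y, a, mean)
  b_mean <- tapply(y, b, mean)
  ss_a <- sum(tapply(y, a, length) * (a_mean - grand)^2)
  ss_b <- sum(tapply(y, b, length) * (b_mean - grand)^2)
  ss_cells <- sum(n_cell * (cell_mean - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  ss_w <- ss_tot - ss_cells
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_w <- length(y) - nlevels(a) * nlevels(b)
  ms_w <- ss_w / df_w
  list(
    F_a = (ss_a / df_a) / ms_w, F_b = (ss_b / df_b) / ms_w,
    F_ab = (ss_ab / df_ab) / ms_w,
    ss = c(a = ss_a, b = ss_b, ab = ss_ab, within = ss_w, total = ss_tot),
    df = c(a = df_a, b = df_b, ab = df_ab, within = df_w)
  )
}

# 0-based ground-truth onset frames from simulated spike times
truth_frames <- function(spike_times_s, frame_rate_hz = 20) {
  floor(spike_times_s * frame_rate_hz)
}

# pooled F1 of inferred vs true spike trains across neurons
pooled_f1 <- function(inferred_list, truth_list, tol_frames = 1) {
  sc <- purrr::map2_dfr(inferred_list, truth_list, score_spike_match,
                        tol_frames = tol_frames)
  2 * sum(sc$tp) / (sum(sc$n_true) + sum(sc$n_inferred))
}
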