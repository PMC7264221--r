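#' Feature vector for one normalized trace
#'
#' A small, auditable feature set computed on the percent
#' \eqn{\Delta F/F} trace: standard deviation, skewness, kurtosis
#' (excess), maximum amplitude, number of excursions above an amplitude
#' threshold, autocorrelation at a 1-s lag, and the ratio of spectral
#' power below/above a split frequency.  Neuronal transients (sharp
#' rise, 3-s decay) load on skewness, excursion count and the 1-s
#' autocorrelation; slow astrocyte-like waves load on the low-band
#' power; flat artifact traces on the variance.
#'
#' @param values Normalized trace (>= 2 s of samples).
#' @param frame_rate_hz Frames per second.
#' @param excursion_threshold Amplitude (percent \eqn{\Delta F/F}) a
#'   contiguous run must exceed to count as one excursion.
#' @param band_split_hz Frequency splitting the low/high power bands.
#' @return A named numeric vector of 7 features.
#' @export
extract_features <- function(values, frame_rate_hz,
                             excursion_threshold = 0.5,
                             band_split_hz = 0.5) {
  n <- length(values)
  if (n < 2 * frame_rate_hz) {
    abort("trace too short: need at least 2 s of samples for features.")
  }
  above <- values > excursion_threshold
  n_exc <- sum(above & !c(FALSE, above[-n]))  # rising edges
  lag <- max(1L, round(frame_rate_hz))
  ac <- if (sd(values) > 0) {
    acf(values, lag.max = lag, plot = FALSE)$acf[lag + 1]
  } else 0
  pw <- Mod(fft(values - mean(values))[seq_len(floor(n / 2)) + 1])^2
  freq <- (seq_len(floor(n / 2))) * frame_rate_hz / n
  lo <- sum(pw[freq <= band_split_hz])
  hi <- sum(pw[freq > band_split_hz])
  c(
    sd = sd(values),
    skewness = if (sd(values) > 0) e1071::skewness(values) else 0,
    kurtosis = if (sd(values) > 0) e1071::kurtosis(values) else 0,
    max_amp = max(values),
    n_excursions = n_exc,
    autocorr_1s = ac,
    band_ratio = if (hi > 0) lo / hi else 0
  )
}

#' Feature table for a trace table
#'
#' @param traces A normalized-stage [trace_tbl()].
#' @param ... Passed to [extract_features()].
#' @return A tibble with `roi_id` and one column per feature.
#' @export
trace_features <- function(traces, ...) {
  stopifnot(inherits(traces, "trace_tbl"))
  f <- traces$frame_rate_hz[1]
  feats <- purrr::map(traces$values, extract_features, frame_rate_hz = f, ...)
  dplyr::bind_cols(tibble(roi_id = traces$roi_id),
                   as_tibble(do.call(rbind, feats)))
}

# weighted decision stump over all features; vectorised threshold scan
fit_stump <- function(x, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    tot_pos <- sum(w[y > 0])
    # thresholds between distinct consecutive values; cumulative class
    # weight left of each candidate gives both polarities' errors
    pos_left <- cumsum((w * (y > 0))[ord])
    neg_left <- cumsum((w * (y < 0))[ord])
    tot_neg <- sum(w[y < 0])
    err_p <- pos_left + (tot_neg - neg_left)   # +1 side is x > thr
    err_m <- neg_left + (tot_pos - pos_left)   # +1 side is x <= thr
    valid <- c(diff(xs) > 0, FALSE)
    if (!any(valid)) next
    for (pol in c(1, -1)) {
      e <- if (pol == 1) err_p else err_m
      e[!valid] <- Inf
      i <- which.min(e)
      if (e[i] < best$err) {
        best <- list(err = e[i], feature = j,
                     threshold = (xs[i] + xs[i + 1]) / 2, polarity = pol)
      }
    }
  }
  if (!is.finite(best$err)) {
    # all features constant: trivial stump predicting the heavier class
    best <- list(err = min(sum(w[y > 0]), sum(w[y < 0])), feature = 1L,
                 threshold = Inf,
                 polarity = if (sum(w * y) >= 0) -1 else 1)
  }
  best
}

stump_predict <- function(stump, x) {
  s <- ifelse(x[, stump$feature] > stump$threshold, 1, -1)
  stump$polarity * s
}

#' Train the boosted trace classifier
#'
#' Discrete AdaBoost over depth-1 decision stumps.  Initial sample
#' weights are inverse to class frequency, so the minority class is not
#' swamped.  Training is deterministic (exhaustive stump search, no
#' random draws); `seed` is accepted for interface stability.
#'
#' @param features Tibble from [trace_features()] (`roi_id` + feature
#'   columns).
#' @param labels Tibble with `roi_id` and `class`
#'   (`"neuronal"`/`"non_neuronal"`), e.g. from [manual_labels()].
#' @param n_rounds Number of weak learners (default 50).
#' @param seed Unused placeholder for deterministic training.
#' @return An object of class `trace_classifier` with the stump
#'   ensemble, feature names and training accuracy.
#' @export
train_classifier <- function(features, labels, n_rounds = 50, seed = NULL) {
  dat <- dplyr::inner_join(features, labels, by = "roi_id")
  if (nrow(dat) == 0) abort("no labelled traces to train on.")
  if (length(unique(dat$class)) < 2) {
    abort("training set must contain both classes.")
  }
  feat_names <- setdiff(names(features), "roi_id")
  x <- as.matrix(dat[feat_names])
  y <- ifelse(dat$class == "neuronal", 1, -1)
  w <- ifelse(y > 0, 1 / sum(y > 0), 1 / sum(y < 0))
  w <- w / sum(w)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    st <- fit_stump(x, y, w)
    pred <- stump_predict(st, x)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break  # perfectly separated
  }
  model <- structure(
    list(stumps = stumps, alphas = alphas, features = feat_names),
    class = "trace_classifier"
  )
  scores <- classifier_score(model, x)
  model$training_accuracy <- mean(sign(scores) == y)
  model
}

classifier_score <- function(model, x) {
  if (length(model$stumps) == 0) return(rep(0, nrow(x)))
  preds <- vapply(model$stumps, stump_predict, numeric(nrow(x)), x = x)
  as.vector(preds %*% model$alphas)
}

#' @export
print.trace_classifier <- function(x, ...) {
  cat(sprintf("<trace_classifier> %d stumps, training accuracy %.3f\n",
              length(x$stumps), x$training_accuracy))
  invisible(x)
}

#' Classify traces with a trained model
#'
#' @param model A [train_classifier()] model.
#' @param features Feature tibble (`roi_id` + the model's feature
#'   columns).
#' @return A tibble `roi_id, class, source = "predicted", score`;
#'   positive scores vote neuronal.
#' @export
classify_traces <- function(model, features) {
  stopifnot(inherits(model, "trace_classifier"))
  if (!all(model$features %in% names(features))) {
    abort("feature columns do not match the trained model.")
  }
  if (nrow(features) == 0) {
    return(tibble(roi_id = integer(), class = character(),
                  source = character(), score = numeric()))
  }
  s <- classifier_score(model, as.matrix(features[model$features]))
  tibble(
    roi_id = features$roi_id,
    class = ifelse(s >= 0, "neuronal", "non_neuronal"),
    source = "predicted",
    score = s
  )
}

#' Build a manual label table
#'
#' @param roi_id Integer ids.
#' @param class `"neuronal"` or `"non_neuronal"` per id.
#' @return A tibble `roi_id, class, source = "manual", round = 0`.
#' @export
manual_labels <- function(roi_id, class) {
  if (!all(class %in% c("neuronal", "non_neuronal"))) {
    abort('`class` must be "neuronal" or "non_neuronal".')
  }
  if (anyDuplicated(roi_id)) abort("duplicate roi_id in labels.")
  tibble(roi_id = as.integer(roi_id), class = class,
         source = "manual", round = 0L)
}

#' Refine a training label set with corrections
#'
#' Mirrors the visual-inspection loop: corrections override prior
#' labels for their ids, the refinement round counter is incremented,
#' and every superseded label is kept in the `audit` attribute.
#'
#' @param labels Current label tibble (from [manual_labels()] or a
#'   previous refinement).
#' @param corrections Tibble `roi_id, class` of corrected labels; ids
#'   must already exist in `labels`.
#' @return The updated label tibble (corrections marked
#'   `source = "manual"`, `round` incremented), with attribute
#'   `"audit"` accumulating replaced rows.
#' @export
refine_training_set <- function(labels, corrections) {
  if (nrow(corrections) == 0) return(labels)
  unknown <- setdiff(corrections$roi_id, labels$roi_id)
  if (length(unknown) > 0) {
    abort(sprintf("corrections reference unknown roi_id: %s",
                  paste(unknown, collapse = ", ")))
  }
  round_next <- max(labels$round %||% 0L) + 1L
  audit <- rbind(attr(labels, "audit"),
                 labels[labels$roi_id %in% corrections$roi_id, ])
  hit <- match(corrections$roi_id, labels$roi_id)
  labels$class[hit] <- corrections$class
  labels$source[hit] <- "manual"
  labels$round[hit] <- round_next
  attr(labels, "audit") <- audit
  labels
}
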