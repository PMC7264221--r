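#' Single-exponential calcium transient model
#'
#' The fluorescence response of one action potential is modelled as an
#' instantaneous-rise, single-exponential-decay transient in percent
#' \eqn{\Delta F/F_0} units that superposes linearly across spikes
#' (non-saturating dynamics).  The same fixed kernel is used for every
#' neuron and every recording.
#'
#' @param amplitude_pct Peak amplitude of the transient evoked by one
#'   spike, in percent \eqn{\Delta F/F_0}.  Default 1.
#' @param decay_s Exponential decay time constant \eqn{\tau}, seconds.
#'   Default 3.
#'
#' @return An object of class `calcium_transient` with fields
#'   `amplitude_pct`, `decay_s` and `saturating` (always `FALSE`).
#' @examples
#' calcium_transient()
#' @export
calcium_transient <- function(amplitude_pct = 1, decay_s = 3) {
  if (!is.numeric(amplitude_pct) || length(amplitude_pct) != 1 ||
      !is.finite(amplitude_pct) || amplitude_pct <= 0) {
    abort("`amplitude_pct` must be a single positive number.")
  }
  if (!is.numeric(decay_s) || length(decay_s) != 1 ||
      !is.finite(decay_s) || decay_s <= 0) {
    abort("`decay_s` must be a single positive number.")
  }
  structure(
    list(amplitude_pct = amplitude_pct, decay_s = decay_s, saturating = FALSE),
    class = "calcium_transient"
  )
}

#' @export
print.calcium_transient <- function(x, ...) {
  cat(sprintf(
    "<calcium_transient> amplitude %.3g%% dF/F0, decay %.3g s, non-saturating\n",
    x$amplitude_pct, x$decay_s
  ))
  invisible(x)
}

#' Discrete transient template (peeling kernel)
#'
#' Samples the transient model on the frame grid:
#' \eqn{k_j = A \exp(-j / (\tau f))} for \eqn{j = 0, 1, \ldots}, where
#' \eqn{f} is the frame rate.  The template is truncated at the first
#' frame where it falls below 1% of its amplitude (and never exceeds
#' `n_frames` samples).
#'
#' @param model A [calcium_transient()].
#' @param n_frames Maximum template length in frames.
#' @param frame_rate_hz Acquisition frame rate, frames per second.
#'
#' @return Numeric vector of template values, `k[1]` being the spike
#'   (onset) frame.
#' @examples
#' k <- transient_template(calcium_transient(), 500, 20)
#' k[1]        # the amplitude
#' k[61] * exp(1)  # ~ the amplitude again: frame 60 is one decay constant
#' @export
transient_template <- function(model, n_frames, frame_rate_hz) {
  stopifnot(inherits(model, "calcium_transient"))
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be positive.")
  tau_f <- model$decay_s * frame_rate_hz
  # k < 1% of amplitude  <=>  j > tau_f * log(100)
  keep <- min(n_frames, floor(tau_f * log(100)) + 1L)
  model$amplitude_pct * exp(-(seq_len(keep) - 1) / tau_f)
}
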