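#' Write / read traces as tabular text
#'
#' One column per ROI (header `roi_<id>`), one row per frame,
#' tab-separated — the interchange format for trace tables.
#'
#' @param traces A [trace_tbl()].
#' @param path Output `.tsv` path.
#' @return `write_traces_tsv()` returns `path` invisibly;
#'   `read_traces_tsv()` returns a [trace_tbl()].
#' @export
write_traces_tsv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_tbl"))
  m <- do.call(cbind, traces$values)
  colnames(m) <- sprintf("roi_%d", traces$roi_id)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_tsv
#' @param frame_rate_hz Frame rate to attach on read.
#' @param stage Processing stage to attach on read.
#' @export
read_traces_tsv <- function(path, frame_rate_hz = 20, stage = "raw") {
  m <- utils::read.delim(path, check.names = FALSE)
  ids <- as.integer(sub("^roi_", "", names(m)))
  trace_tbl(ids, as.list(m), frame_rate_hz, stage)
}

#' Write spike trains as tabular text
#'
#' Long format: one row per spike with `roi_id`, `frame` (0-based),
#' `time_s` and `window`.
#'
#' @param spikes An [infer_spikes()] table.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_spikes_tsv <- function(spikes, path) {
  long <- purrr::pmap_dfr(
    list(spikes$roi_id, spikes$window, spikes$spike_frames,
         spikes$spike_times_s),
    function(id, w, fr, ts) {
      tibble(roi_id = id, frame = fr, time_s = ts, window = w)
    }
  )
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
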