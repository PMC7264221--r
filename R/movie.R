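#' Fluorescence movie container
#'
#' A time-ordered stack of 2-D intensity frames at a fixed frame rate,
#' stored as a `rows x cols x frames` array.
#'
#' @param frames 3-D numeric array `[row, col, frame]`, nonnegative.
#' @param frame_rate_hz Frames per second (> 0).
#' @return An object of class `fluor_movie`.
#' @export
fluor_movie <- function(frames, frame_rate_hz) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a rows x cols x frames array.")
  }
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be positive.")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fluor_movie> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' Lay out non-overlapping circular somata on a canvas
#'
#' Places `n` soma centres on a jittered square grid with guaranteed
#' centre-to-centre spacing of at least `4 * radius`, so Gaussian
#' footprints do not overlap appreciably.
#'
#' @param n Number of somata.
#' @param dim Canvas size, `c(rows, cols)`.
#' @param radius Soma radius in pixels (Gaussian sd is `radius / 2`).
#' @param seed Seed for the jitter.
#' @return A tibble `roi_id, row, col, radius`.
#' @export
soma_layout <- function(n, dim = c(128, 128), radius = 4, seed = 1L) {
  cell <- 4 * radius
  margin <- 2 * radius
  rows_avail <- floor((dim[1] - 2 * margin) / cell) + 1
  cols_avail <- floor((dim[2] - 2 * margin) / cell) + 1
  if (n > 0 && (rows_avail < 1 || cols_avail < 1 ||
                rows_avail * cols_avail < n)) {
    abort(sprintf("canvas %dx%d too small for %d somata of radius %g.",
                  dim[1], dim[2], n, radius))
  }
  if (n == 0) {
    return(tibble(roi_id = integer(), row = numeric(), col = numeric(),
                  radius = numeric()))
  }
  grid <- expand.grid(
    row = margin + cell * (seq_len(rows_avail) - 1),
    col = margin + cell * (seq_len(cols_avail) - 1)
  )
  withr::with_seed(seed, {
    pick <- sample.int(nrow(grid), n)
    jit <- matrix(runif(2 * n, -radius / 2, radius / 2), ncol = 2)
  })
  tibble(
    roi_id = seq_len(n),
    row = grid$row[pick] + jit[, 1],
    col = grid$col[pick] + jit[, 2],
    radius = radius
  )
}

#' Render a synthetic fluorescence movie from traces
#'
#' Each frame is a constant background plus, per soma, a 2-D Gaussian
#' footprint (peak 1, sd `radius / 2`) scaled by that neuron's trace
#' value at that frame, plus pixel-wise Gaussian noise.
#'
#' @param traces A raw-stage [trace_tbl()], one row per soma.
#' @param layout A [soma_layout()] with one row per trace.
#' @param dim Canvas size `c(rows, cols)`.
#' @param background Constant background intensity.
#' @param pixel_noise_sd Pixel noise standard deviation.
#' @param seed Seed for the pixel noise; `NULL` for noiseless frames.
#' @return A [fluor_movie()].
#' @export
render_movie <- function(traces, layout, dim = c(128, 128),
                         background = 20, pixel_noise_sd = 0.5,
                         seed = NULL) {
  if (nrow(traces) != nrow(layout)) {
    abort("`traces` and `layout` must have one row per soma.")
  }
  n_px <- dim[1] * dim[2]
  n_frames <- if (nrow(traces) > 0) length(traces$values[[1]]) else 1L
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  if (nrow(layout) > 0) {
    out_of_canvas <- layout$row < 1 | layout$row > dim[1] |
      layout$col < 1 | layout$col > dim[2]
    if (any(out_of_canvas)) abort("soma centres fall outside the canvas.")
    fp <- vapply(seq_len(nrow(layout)), function(i) {
      s <- layout$radius[i] / 2
      as.vector(exp(-((rr - layout$row[i])^2 + (cc - layout$col[i])^2) /
                      (2 * s^2)))
    }, numeric(n_px))
    tm <- t(vapply(traces$values, identity, numeric(n_frames)))
    flat <- fp %*% tm + background
  } else {
    flat <- matrix(background, n_px, n_frames)
  }
  if (!is.null(seed) && pixel_noise_sd > 0) {
    flat <- flat + withr::with_seed(
      seed, matrix(rnorm(n_px * n_frames, 0, pixel_noise_sd), n_px, n_frames)
    )
  }
  fr <- if (nrow(traces) > 0) traces$frame_rate_hz[1] else 20
  fluor_movie(array(flat, c(dim[1], dim[2], n_frames)), frame_rate_hz = fr)
}

#' Write / read a movie as multi-page TIFF
#'
#' Intensities are linearly rescaled to `[0, 1]` on write (32-bit float
#' pages); the scale is recorded so `read_movie_tiff()` restores the
#' original units.
#'
#' @param movie A [fluor_movie()].
#' @param path Output `.tif` path.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a [fluor_movie()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "fluor_movie"))
  hi <- max(movie$frames)
  pages <- lapply(seq_len(dim(movie$frames)[3]), function(t) {
    movie$frames[, , t] / hi
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(
    sprintf("scale\t%.17g\nframe_rate_hz\t%.17g", hi, movie$frame_rate_hz),
    paste0(path, ".meta.tsv")
  )
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate_hz Frame rate to assume when no side-car metadata
#'   file is present.
#' @export
read_movie_tiff <- function(path, frame_rate_hz = 20) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, header = FALSE)
    scale <- as.numeric(meta$V2[meta$V1 == "scale"])
    frame_rate_hz <- as.numeric(meta$V2[meta$V1 == "frame_rate_hz"])
  }
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  fluor_movie(arr * scale, frame_rate_hz)
}
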