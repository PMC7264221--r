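#' Time-average a movie
#'
#' Pixel-wise arithmetic mean over all frames; averaging across the
#' whole recording gives a clear picture of the cell bodies on which
#' ROI detection operates.
#'
#' @param movie A [fluor_movie()].
#' @return A `rows x cols` numeric matrix.
#' @export
time_average <- function(movie) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  if (d[3] < 1) abort("empty movie: no frames to average.")
  rowMeans(movie$frames, dims = 2)
}

# 8-connectivity connected-component labelling (EBImage::bwlabel is
# 4-connected, so diagonal soma pixels would split components)
label_components8 <- function(fg) {
  d <- dim(fg)
  lab <- matrix(0L, d[1], d[2])
  todo <- which(fg)
  nb <- c(-1L, 1L, -d[1], d[1], -d[1] - 1L, -d[1] + 1L, d[1] - 1L, d[1] + 1L)
  cur <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- ((p - 1L) %% d[1]) + 1L
      cand <- p + nb
      keep <- cand >= 1L & cand <= d[1] * d[2]
      # forbid wrap-around across matrix columns
      keep <- keep & abs(((cand - 1L) %% d[1]) + 1L - r) <= 1L
      cand <- cand[keep]
      cand <- cand[fg[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      queue <- c(queue, cand)
    }
  }
  lab
}

#' Detect cell-body ROIs on a time-averaged image
#'
#' Foreground is taken as pixels above a global Otsu threshold of the
#' time-averaged image; 8-connected components are filtered to the
#' plausible soma area range and returned as pixel masks with ids
#' assigned in raster order of their centroids.
#'
#' @param avg_image 2-D intensity matrix (e.g. from [time_average()]).
#' @param min_area_px,max_area_px Component area limits in pixels
#'   (defaults 20-600, suited to a x10-objective field of view).
#' @param drop_border Drop components touching the image border.
#'
#' @return A tibble of class `roi_tbl`: `roi_id`, `area_px`,
#'   `centroid_row`, `centroid_col`, and `pixels`, a list-column of
#'   2-column `(row, col)` matrices (1-based).  A uniform image yields
#'   zero rows with a warning.
#' @export
detect_rois <- function(avg_image, min_area_px = 20, max_area_px = 600,
                        drop_border = FALSE) {
  if (min_area_px > max_area_px) abort("`min_area_px` must be <= `max_area_px`.")
  rng <- range(avg_image)
  empty <- tibble(roi_id = integer(), area_px = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  pixels = list())
  if (diff(rng) == 0) {
    warn("uniform image: no threshold separates foreground; returning 0 ROIs.")
    return(empty)
  }
  scaled <- (avg_image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled))
  fg <- scaled > thr
  lab <- label_components8(fg)
  if (max(lab) == 0L) {
    warn("no foreground components found; returning 0 ROIs.")
    return(empty)
  }
  comps <- purrr::map(seq_len(max(lab)), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    px
  })
  keep <- purrr::map_lgl(comps, function(px) {
    n <- nrow(px)
    ok <- n >= min_area_px && n <= max_area_px
    if (ok && drop_border) {
      ok <- !any(px[, 1] == 1 | px[, 1] == nrow(avg_image) |
                   px[, 2] == 1 | px[, 2] == ncol(avg_image))
    }
    ok
  })
  comps <- comps[keep]
  if (length(comps) == 0) return(empty)
  cr <- purrr::map_dbl(comps, ~ mean(.x[, 1]))
  cc <- purrr::map_dbl(comps, ~ mean(.x[, 2]))
  ord <- order(cr, cc)  # raster order of centroids
  out <- tibble(
    roi_id = seq_along(comps),
    area_px = purrr::map_int(comps[ord], nrow),
    centroid_row = cr[ord],
    centroid_col = cc[ord],
    pixels = comps[ord]
  )
  class(out) <- c("roi_tbl", class(out))
  out
}

#' Extract per-ROI traces by spatial averaging
#'
#' The trace of each ROI is the mean over its pixels of every frame.
#'
#' @param movie A [fluor_movie()].
#' @param rois A [detect_rois()] table.
#' @return A raw-stage [trace_tbl()], one row per ROI, trace length
#'   equal to the number of frames.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  vals <- purrr::map2(rois$pixels, rois$roi_id, function(px, id) {
    if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2])) {
      abort(sprintf("ROI %d has pixels outside the frame bounds.", id))
    }
    idx <- (px[, 2] - 1L) * d[1] + px[, 1]
    colMeans(flat[idx, , drop = FALSE])
  })
  trace_tbl(rois$roi_id, vals, movie$frame_rate_hz, "raw")
}

#' Convert an ROI table to a label image
#'
#' @param rois A [detect_rois()] table.
#' @param dim Image size `c(rows, cols)`.
#' @return Integer matrix with each ROI's pixels set to its id.
#' @export
roi_label_image <- function(rois, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(rois))) {
    px <- rois$pixels[[i]]
    lab[(px[, 2] - 1L) * dim[1] + px[, 1]] <- rois$roi_id[i]
  }
  lab
}
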