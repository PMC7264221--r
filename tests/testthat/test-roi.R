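make_disc_image <- function(dim = c(64, 64), centers, radius = 4,
                            fg = 10, bg = 1) {
  img <- matrix(bg, dim[1], dim[2])
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(centers))) {
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2] <- fg
  }
  img
}

test_that("time averaging is the pixelwise mean", {
  frames <- array(0, c(4, 4, 2))
  frames[, , 2] <- 2
  mv <- fluor_movie(frames, 20)
  expect_equal(time_average(mv), matrix(1, 4, 4))
  same <- fluor_movie(array(3, c(4, 4, 5)), 20)
  expect_equal(time_average(same), matrix(3, 4, 4))
})

test_that("time average of a constant-trace movie matches the template", {
  cfg <- sim_config(n_neurons = 3, duration_s = 5, frame_rate_hz = 20,
                    basal_rate_hz = 0, silent_fraction = 0, noise_sd = 0,
                    drift_amplitude = 0, seed = 2L)
  st <- simulate_spike_trains(cfg, "basal")
  tr <- render_traces(st, cfg)
  lay <- soma_layout(3, dim = c(64, 64), radius = 4, seed = 3L)
  noiseless <- render_movie(tr, lay, dim = c(64, 64), pixel_noise_sd = 0)
  noisy <- render_movie(tr, lay, dim = c(64, 64), pixel_noise_sd = 0.5,
                        seed = 4L)
  tmpl <- noiseless$frames[, , 1]
  avg <- time_average(noisy)
  # residual noise scales as sd / sqrt(T)
  expect_lt(max(abs(avg - tmpl)), 6 * 0.5 / sqrt(100))
})

test_that("disc images yield one ROI per disc at its centroid", {
  centers <- rbind(c(15, 15), c(15, 45), c(45, 30))
  img <- make_disc_image(centers = centers)
  rois <- detect_rois(img)
  expect_equal(nrow(rois), 3)
  got <- as.matrix(rois[, c("centroid_row", "centroid_col")])
  ord <- order(centers[, 1], centers[, 2])
  expect_true(all(abs(got - centers[ord, ]) <= 1))
  # pixel sets are pairwise disjoint
  keys <- unlist(purrr::map(rois$pixels, ~ paste(.x[, 1], .x[, 2])))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("uniform images yield zero ROIs with a warning", {
  expect_warning(rois <- detect_rois(matrix(5, 32, 32)), "uniform")
  expect_equal(nrow(rois), 0)
})

test_that("detection uses 8-connectivity and respects area limits", {
  img <- matrix(0, 20, 20)
  img[5:8, 5:8] <- 10       # 16 px blob
  img[9, 9] <- 10           # diagonally attached pixel -> same component
  rois <- detect_rois(img, min_area_px = 17, max_area_px = 600)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$area_px, 17L)
  expect_equal(nrow(detect_rois(img, min_area_px = 18, max_area_px = 600)), 0)
})

test_that("trace extraction spatially averages ROI pixels", {
  frames <- array(seq_len(4 * 4 * 3), c(4, 4, 3))
  mv <- fluor_movie(frames, 20)
  one_px <- tibble::tibble(roi_id = 1L,
                           pixels = list(cbind(row = 2L, col = 3L)))
  tr <- extract_traces(mv, one_px)
  expect_equal(tr$values[[1]], frames[2, 3, ])
  const <- fluor_movie(array(7, c(4, 4, 3)), 20)
  region <- tibble::tibble(roi_id = 1L,
                           pixels = list(cbind(row = c(1L, 2L), col = c(1L, 1L))))
  expect_equal(extract_traces(const, region)$values[[1]], rep(7, 3))
  oob <- tibble::tibble(roi_id = 9L, pixels = list(cbind(row = 9L, col = 1L)))
  expect_error(extract_traces(mv, oob), "ROI 9")
})

test_that("extraction is linear in the movie", {
  a <- fluor_movie(array(runif(4 * 4 * 5), c(4, 4, 5)), 20)
  b <- fluor_movie(array(runif(4 * 4 * 5), c(4, 4, 5)), 20)
  ab <- fluor_movie(a$frames + b$frames, 20)
  rois <- tibble::tibble(roi_id = 1L,
                         pixels = list(cbind(row = c(1L, 3L), col = c(2L, 4L))))
  expect_equal(extract_traces(ab, rois)$values[[1]],
               extract_traces(a, rois)$values[[1]] +
                 extract_traces(b, rois)$values[[1]],
               tolerance = 1e-12)
})

test_that("somata are recovered end-to-end from a synthetic movie", {
  cfg <- sim_config(n_neurons = 25, duration_s = 10, basal_rate_hz = 0.2,
                    silent_fraction = 0, noise_sd = 0.2, seed = 21L)
  st <- simulate_spike_trains(cfg, "basal")
  tr <- render_traces(st, cfg)
  lay <- soma_layout(25, dim = c(128, 128), radius = 4, seed = 22L)
  mv <- render_movie(tr, lay, dim = c(128, 128), background = 20,
                     pixel_noise_sd = 0.5, seed = 23L)
  rois <- detect_rois(time_average(mv), min_area_px = 10, max_area_px = 600)
  matched <- purrr::map_lgl(seq_len(25), function(i) {
    d <- sqrt((rois$centroid_row - lay$row[i])^2 +
                (rois$centroid_col - lay$col[i])^2)
    any(d <= lay$radius[i])
  })
  expect_gte(sum(matched), 24)  # >= 95% of ground-truth somata
  # extracted soma traces track the generating traces
  ex <- extract_traces(mv, rois)
  i <- which.min((rois$centroid_row - lay$row[1])^2 +
                   (rois$centroid_col - lay$col[1])^2)
  expect_gt(cor(ex$values[[i]], tr$values[[1]]), 0.95)
})

test_that("movies survive a TIFF round trip", {
  mv <- fluor_movie(array(runif(8 * 8 * 4, 0, 50), c(8, 8, 4)), 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path)
  expect_equal(back$frame_rate_hz, 20)
  expect_equal(back$frames, mv$frames, tolerance = 1e-6)
})

test_that("layouts refuse a canvas that cannot hold the somata", {
  expect_error(soma_layout(100, dim = c(32, 32), radius = 4), "too small")
  expect_equal(nrow(render_movie(trace_tbl(integer(), list(), 20),
                                 soma_layout(0))$frames[, , 1]), 128)
})
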