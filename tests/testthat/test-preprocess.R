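test_that("ROI crop keeps 51 columns at default geometry and is idempotent", {
  cfg <- sim_config(seed = 7)
  cube <- simulate_sample(1, 2, cfg)
  expect_equal(cube$pixel_pitch_mm, 0.2)
  cropped <- crop_roi(cube)
  expect_identical(dim(cropped$data)[2], 51L)
  expect_identical(cropped$laser_col, 26L)
  expect_true(all(cropped$shift_cm1 >= 600 - 1e-6 &
                    cropped$shift_cm1 <= 1800 + 1e-6))
  expect_identical(crop_roi(cropped), cropped)
})

test_that("degenerate and invalid ROIs are handled", {
  cube <- toy_cube()
  cfg0 <- preprocess_config(roi_halfwidth_mm = 0)
  expect_identical(dim(crop_roi(cube, cfg0)$data)[2], 1L)
  edge <- toy_cube(n_pixels = 9)
  edge$laser_index <- 2L
  expect_error(crop_roi(edge, preprocess_config(roi_halfwidth_mm = 0.8)),
               class = "sors_roi_error")
})

test_that("peak detector finds constructed peaks and nothing in flat spectra", {
  shift <- seq(600, 1800, by = 2)
  expect_length(detect_typical_peaks(rep(3, length(shift)), shift), 0)
  single <- exp(-0.5 * ((shift - 1003) / 8)^2)
  pk <- detect_typical_peaks(single, shift)
  expect_length(pk, 1)
  expect_lt(abs(pk - 1003), 4)
})

test_that("anomalous positions are flagged exactly; vacuous threshold keeps all", {
  cfg <- small_sim_config(anomaly_rate = 0.08, noise_sd = 0.01)
  refs <- generate_reference_spectra(cfg)
  cube <- simulate_sample(3, 2, cfg)
  x <- crop_roi(cube)
  truth <- x$anomaly_pixels
  expect_gt(length(truth), 0)
  flagged <- remove_anomalous_spectra(x, refs$meat)
  expect_identical(which(flagged$excluded), as.integer(truth))
  expect_identical(flagged$n_anomalies_removed, length(truth))

  clean <- crop_roi(simulate_sample(3, 2, small_sim_config(anomaly_rate = 0)))
  expect_identical(
    remove_anomalous_spectra(clean, refs$meat)$n_anomalies_removed, 0L)

  vac <- preprocess_config(min_peaks_matched = 0)
  expect_identical(
    remove_anomalous_spectra(x, refs$meat, vac)$n_anomalies_removed, 0L)
})

test_that("a sample whose positions are all anomalous is rejected", {
  cfg <- small_sim_config(anomaly_rate = 1)
  refs <- generate_reference_spectra(cfg)
  cube <- crop_roi(simulate_sample(1, 1, cfg))
  expect_error(remove_anomalous_spectra(cube, refs$meat),
               class = "sors_sample_rejected")
})

test_that("cosmic-ray trimming equals the sort-drop-average oracle", {
  expect_equal(trimmed_repeat_mean(c(1, 1, 1, 1, 100)), 1)
  expect_equal(trimmed_repeat_mean(rep(5, 4)), 5)
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(10)
    oracle <- mean(sort(x)[2:9])  # sort, drop extremes, average
    expect_equal(trimmed_repeat_mean(x), oracle)
  }
  expect_error(trimmed_repeat_mean(c(1, 2)), class = "sors_input_error")
})

test_that("trimmed cube averaging matches per-cell oracles", {
  cube <- as_cropped(toy_cube(n_repeats = 6), roi_halfwidth_mm = 0.8)
  set.seed(1)
  cube$data <- array(rnorm(length(cube$data)), dim = dim(cube$data))
  expect_error(remove_cosmic_rays(toy_cube(n_repeats = 2)),
               class = "sors_input_error")
  trimmed <- remove_cosmic_rays(cube)
  img <- average_and_smooth(trimmed, preprocess_config(sg_window = 5,
                                                       sg_polyorder = 1))
  # compare one unsmoothed cell against the brute-force trimmed mean by
  # reconstructing the trimmed mean image directly
  tm <- with(trimmed$trim_stats, (sum - max - min) / (n - 2))
  oracle <- apply(cube$data, c(2, 3), function(v) mean(sort(v)[2:5]))
  expect_equal(tm, oracle)
  expect_identical(dim(img$intensity), dim(tm))
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials and reduces noise", {
  shift <- seq(600, 1800, length.out = 60)
  const <- toy_cube(values = matrix(2.5, 9, 60), shift = shift)
  img <- average_and_smooth(as_cropped(const, 0.8))
  expect_equal(img$intensity, matrix(2.5, 9, 60), tolerance = 1e-10)

  x <- seq_len(60)
  cubic <- matrix(rep(0.1 * x^3 - 2 * x^2 + x, each = 9), 9, 60)
  img2 <- average_and_smooth(as_cropped(toy_cube(values = cubic,
                                                 shift = shift), 0.8))
  expect_equal(img2$intensity, cubic, tolerance = 1e-8)

  set.seed(3)
  noisy <- matrix(rep(sin(x / 4), each = 9), 9, 60) +
    matrix(rnorm(9 * 60, 0, 0.3), 9, 60)
  img3 <- average_and_smooth(as_cropped(toy_cube(n_repeats = 3,
                                                 values = noisy,
                                                 shift = shift), 0.8))
  resid_in <- noisy - matrix(rep(sin(x / 4), each = 9), 9, 60)
  resid_out <- img3$intensity - matrix(rep(sin(x / 4), each = 9), 9, 60)
  expect_lt(var(as.vector(resid_out)), var(as.vector(resid_in)))

  expect_error(average_and_smooth(as_cropped(toy_cube(), 0.8),
                                  preprocess_config(sg_window = 51)),
               class = "sors_config_error")
})

test_that("adjacent-band averaging forms exact block means", {
  shift <- seq(600, 1800, length.out = 10)
  ramp <- matrix(rep(1:10, each = 9), 9, 10)
  img <- as_cropped(toy_cube(values = ramp, shift = shift), 0.8)
  img <- average_and_smooth(img, preprocess_config(sg_window = 5,
                                                   sg_polyorder = 1))
  img$intensity <- ramp  # bypass smoothing for the arithmetic check
  out <- band_average(img, 2L)
  expect_equal(out$intensity, matrix(rep(c(3, 8), each = 9), 9, 2))
  expect_equal(out$band_centers_cm1,
               c(mean(shift[1:5]), mean(shift[6:10])))
  const <- img; const$intensity <- matrix(4, 9, 10)
  expect_true(all(band_average(const, 5L)$intensity == 4))
  expect_error(band_average(img, 3L), class = "sors_config_error")
})

test_that("offset folding averages mirror columns and bins distances", {
  shift <- seq(600, 1800, length.out = 12)
  vals <- matrix(0, 9, 12)
  vals[1, ] <- 0; vals[9, ] <- 2  # same |d|, average 1
  img <- as_cropped(toy_cube(values = vals, shift = shift), 0.8)
  img <- average_and_smooth(img, preprocess_config(sg_window = 5,
                                                   sg_polyorder = 1))
  img$intensity <- vals
  out <- fold_offsets(img, 5L)
  expect_equal(out$matrix[, 5], rep(1, 12))
  expect_equal(out$offsets_mm, seq(0, 0.8, by = 0.2))

  # mirror-symmetric image: folding is the identity on the right half
  sym <- img
  sym$intensity <- matrix(rep(abs(-4:4), 12), 9, 12)
  folded <- fold_offsets(sym, 5L)
  expect_equal(folded$matrix, t(sym$intensity[5:9, ]))

  even <- img
  even$intensity <- even$intensity[1:8, ]
  even$pixel_offsets_mm <- even$pixel_offsets_mm[1:8]
  even$excluded <- even$excluded[1:8]
  expect_error(fold_offsets(even, 5L), class = "sors_geometry_error")
})

test_that("the full chain yields the 200 x 11 matrix with the stated axes", {
  cfg <- sim_config(seed = 5)
  refs <- generate_reference_spectra(cfg)
  p <- preprocess_sample(simulate_sample(2, 6, cfg), refs$meat)
  expect_identical(dim(p$matrix), c(200L, 11L))
  expect_equal(p$offsets_mm, seq(0, 5, by = 0.5))
  expect_identical(length(p$band_centers_cm1), 200L)
  expect_false(is.unsorted(p$band_centers_cm1, strictly = TRUE))
  expect_true(all(is.finite(p$matrix)) && all(p$matrix >= 0))
  expect_identical(p$day, 6L)
})

test_that("spatially mirroring the raw cube leaves the output unchanged", {
  cfg <- small_sim_config()
  refs <- generate_reference_spectra(cfg)
  cube <- simulate_sample(1, 4, cfg)
  mirrored <- cube
  np <- dim(cube$data)[2]
  mirrored$data <- cube$data[, np:1, , drop = FALSE]
  mirrored$laser_index <- np + 1L - cube$laser_index
  mirrored$anomaly_pixels <- np + 1L - cube$anomaly_pixels
  a <- preprocess_sample(cube, refs$meat)
  b <- preprocess_sample(mirrored, refs$meat)
  expect_equal(a$matrix, b$matrix)
})

test_that("single injected spikes are fully absorbed by the trimming", {
  cfg <- clean_sim_config()
  refs <- generate_reference_spectra(cfg)
  cube <- simulate_sample(2, 3, cfg)
  spiked <- cube
  set.seed(8)
  for (r in seq_len(dim(cube$data)[1])) {
    px <- sample(dim(cube$data)[2], 1)
    bd <- sample(dim(cube$data)[3], 1)
    spiked$data[r, px, bd] <- spiked$data[r, px, bd] + 50
  }
  a <- preprocess_sample(cube, refs$meat)
  b <- preprocess_sample(spiked, refs$meat)
  expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
})

test_that("anomaly flagging has high precision and recall at default rates", {
  cfg <- small_sim_config(n_shrimp = 10, n_days = 2, seed = 202)
  refs <- generate_reference_spectra(cfg)
  meta <- dataset_metadata(cfg)
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(meta))) {
    cube <- crop_roi(simulate_sample(meta$shrimp_id[i], meta$day[i], cfg))
    flagged <- remove_anomalous_spectra(cube, refs$meat)
    truth <- cube$anomaly_pixels
    got <- which(flagged$excluded)
    tp <- tp + length(intersect(truth, got))
    fp <- fp + length(setdiff(got, truth))
    fn <- fn + length(setdiff(truth, got))
  }
  expect_gt(tp, 10)  # enough positives for the rates to be meaningful
  expect_gte(tp / (tp + fp), 0.95)
  expect_gte(tp / (tp + fn), 0.95)
})
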