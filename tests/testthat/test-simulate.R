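test_that("meat reference peaks sit at the configured centers; shell is peak-free", {
  cfg <- small_sim_config()
  refs <- generate_reference_spectra(cfg)
  det <- detect_typical_peaks(refs$meat$intensity, refs$meat$shift_cm1)
  for (p in cfg$peak_centers) {
    expect_lt(min(abs(det - p)), 5)
  }
  expect_length(
    detect_typical_peaks(refs$shell$intensity, refs$shell$shift_cm1), 0)
  expect_identical(refs$meat$typical_peaks,
                   c(1003, 1148, 1269, 1311, 1487))
  expect_true(all(refs$meat$intensity >= 0) && all(refs$shell$intensity >= 0))
})

test_that("zero peak amplitudes leave only the baseline", {
  cfg <- small_sim_config(peak_amplitudes = rep(0, 5))
  refs <- generate_reference_spectra(cfg)
  base <- 0.08 + 0.02 * (refs$meat$shift_cm1 - 600) / 1200
  expect_equal(refs$meat$intensity, base)
})

test_that("peak centers outside the band of interest are rejected", {
  expect_error(sim_config(peak_centers = c(1003, 2100)),
               class = "sors_config_error")
})

test_that("noiseless cubes are mirror-symmetric about the laser pixel", {
  cfg <- clean_sim_config()
  cube <- simulate_sample(1, 3, cfg)
  li <- cube$laser_index
  for (k in c(1, 5, 20)) {
    expect_equal(cube$data[2, li - k, ], cube$data[2, li + k, ])
  }
})

test_that("protein peak amplitude decays geometrically with storage day", {
  cfg <- clean_sim_config()
  li <- simulate_sample(1, 1, cfg)$laser_index
  native_shift <- seq(600, 1800, length.out = 400)
  band <- which.min(abs(native_shift - 1269))
  side <- which.min(abs(native_shift - 1229))  # off-peak baseline band
  amp <- vapply(1:7, function(d) {
    cube <- simulate_sample(1, d, cfg)
    cube$data[1, li + 10, band] - cube$data[1, li + 10, side]
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
  # ratio between consecutive days approaches the configured decay factor
  expect_equal(amp[7] / amp[6], 1 - cfg$day_decay_rate, tolerance = 0.05)
})

test_that("mixing weights favour the shell at zero offset and conserve throughput", {
  cfg <- sim_config()
  w0 <- mixing_weights(0, cfg)
  w5 <- mixing_weights(5, cfg)
  expect_gt(w0$shell / w0$meat, w5$shell / w5$meat)
  d <- seq(0, 5, by = 0.1)
  w <- mixing_weights(d, cfg)
  expect_equal(w$shell + w$meat, rep(1, length(d)))
  expect_true(all(diff(w$shell) < 0))
})

test_that("campaign metadata enumerates n_shrimp x n_days samples", {
  expect_identical(nrow(dataset_metadata(sim_config(n_shrimp = 3, n_days = 5))),
                   15L)
  one <- generate_dataset(sim_config(n_shrimp = 1, n_days = 1, n_pixels = 64,
                                     window_mm = 12.8,
                                     native_band_count = 100))
  expect_identical(nrow(one), 1L)
  expect_s3_class(one$cube[[1]], "sors_cube")
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- sim_config(n_shrimp = 2, n_days = 2, n_pixels = 64,
                    window_mm = 12.8, native_band_count = 100, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$cube, b$cube)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(generate_dataset(cfg2)$cube, a$cube))
})

test_that("out-of-range day or shrimp is rejected", {
  cfg <- small_sim_config()
  expect_error(simulate_sample(1, 8, cfg), class = "sors_input_error")
  expect_error(simulate_sample(99, 1, cfg), class = "sors_input_error")
})

test_that("injected artifact counts are recorded and retrievable", {
  cfg <- small_sim_config(cosmic_ray_rate = 0.02, anomaly_rate = 0.1)
  cube <- simulate_sample(2, 4, cfg)
  expect_s3_class(cube$cosmic_rays, "tbl_df")
  expect_gt(nrow(cube$cosmic_rays), 0)
  expect_gt(length(cube$anomaly_pixels), 0)
  expect_true(all(cube$cosmic_rays$pixel %in% seq_len(cfg$n_pixels)))
  clean <- simulate_sample(2, 4, clean_sim_config())
  expect_identical(nrow(clean$cosmic_rays), 0L)
  expect_length(clean$anomaly_pixels, 0)
})

test_that("the 1269 cm^-1 amplitude at the largest offset is monotone in day", {
  cfg <- clean_sim_config()
  refs <- generate_reference_spectra(cfg)
  amp <- vapply(1:7, function(d) {
    p <- preprocess_sample(simulate_sample(1, d, cfg), refs$meat)
    i <- which.min(abs(p$band_centers_cm1 - 1269))
    off <- ncol(p$matrix)
    p$matrix[i, off] - (p$matrix[i - 8, off] + p$matrix[i + 8, off]) / 2
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
})
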