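# Shared fixtures, built in code. The "small instrument" keeps the default
# 0.2 mm pixel pitch (so the ROI is still 51 columns) but a quarter of the
# spatial window and 400 native bands, making per-sample simulation cheap
# while exercising every preprocessing stage. Expensive shared objects are
# memoised for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_sim_config <- function(...) {
  args <- modifyList(list(n_shrimp = 4, n_days = 7, n_pixels = 128,
                          window_mm = 25.6, native_band_count = 400,
                          seed = 101), list(...))
  do.call(sim_config, args)
}

# Noise- and artifact-free variant for closed-form signal checks.
clean_sim_config <- function(...) {
  args <- modifyList(list(noise_sd = 0, anomaly_rate = 0,
                          cosmic_ray_rate = 0, gain_jitter = 0,
                          shell_scale_jitter = 0), list(...))
  do.call(small_sim_config, args)
}

small_processed <- function() {
  memo("small_processed", {
    simulate_processed_dataset(small_sim_config())
  })
}

# A tiny hand-built cube with known polynomial spectra, for stage-level
# arithmetic checks independent of the simulator.
toy_cube <- function(n_repeats = 5, n_pixels = 9, values = NULL,
                     shift = seq(600, 1800, length.out = 40)) {
  nb <- length(shift)
  data <- array(0, dim = c(n_repeats, n_pixels, nb))
  if (is.null(values)) values <- matrix(1, n_pixels, nb)
  for (r in seq_len(n_repeats)) data[r, , ] <- values
  structure(
    list(data = data,
         wavelength_nm = shift_to_wavelength(shift),
         excitation_nm = 785,
         laser_index = (n_pixels + 1L) %/% 2L,
         pixel_pitch_mm = 0.2,
         shrimp_id = 1L, day = 1L,
         anomaly_pixels = integer(0),
         cosmic_rays = tibble::tibble(repeat_id = integer(),
                                      pixel = integer(), band = integer())),
    class = "sors_cube")
}

# Mark a toy/cropped-geometry cube as already cropped so mid-chain stages
# can be tested in isolation.
as_cropped <- function(cube, roi_halfwidth_mm = NULL) {
  cfg <- preprocess_config()
  if (!is.null(roi_halfwidth_mm)) cfg$roi_halfwidth_mm <- roi_halfwidth_mm
  crop_roi(cube, cfg)
}

# Scaled benchmark shared between the acceptance blocks: one seeded run of
# the full model comparison on a 30-shrimp campaign with reduced epochs.
acceptance_benchmark <- function() {
  memo("acceptance_benchmark", {
    freshness_benchmark(n_shrimp = 30L, epochs = 200L, n_repeats = 3L,
                        seed = 1L)
  })
}
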