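# Synthetic SORS data generator: reference spectra, single-sample cubes,
# and whole-campaign datasets. All randomness is derived from cfg$seed so a
# dataset is bit-reproducible sample by sample, in any generation order.

# Per-entity seeds, kept below 2^31. Day 0 indexes shrimp-level draws.
sample_seed <- function(cfg, shrimp_id, day = 0L) {
  as.integer((as.double(cfg$seed) + 7919 * shrimp_id + 104729 * day) %%
               2147483647)
}

# Native Raman shift grid (uniform over the configured range).
native_shift_axis <- function(cfg) {
  seq(cfg$shift_range_cm1[1], cfg$shift_range_cm1[2],
      length.out = cfg$native_band_count)
}

# Shell fluorescence: one broad smooth hump across the window, no narrow
# features. Unit peak height before day scaling.
shell_curve <- function(shift, center = 1150, width = 620) {
  exp(-((shift - center) / width)^2)
}

# A second shell-like curve used at anomalous positions (exoskeleton
# intersections): shifted/flatter fluorescence, still peak-free.
anomaly_curve <- function(shift) {
  0.8 * exp(-((shift - 1350) / 700)^2)
}

# Meat baseline: low, gently sloped.
meat_baseline <- function(shift, cfg) {
  0.08 + 0.02 * (shift - cfg$shift_range_cm1[1]) / diff(cfg$shift_range_cm1)
}

# Meat peak amplitudes on a given storage day: the protein-related peaks
# decay geometrically, the others are stable.
day_peak_amplitudes <- function(cfg, day) {
  amp <- cfg$peak_amplitudes
  dec <- cfg$peak_centers %in% cfg$decaying_peaks
  amp[dec] <- amp[dec] * (1 - cfg$day_decay_rate)^(day - 1)
  amp
}

# Meat spectrum on the native shift axis for a given day.
meat_spectrum <- function(shift, cfg, day = 1) {
  amp <- day_peak_amplitudes(cfg, day)
  y <- meat_baseline(shift, cfg)
  for (k in seq_along(cfg$peak_centers)) {
    y <- y + amp[k] *
      exp(-0.5 * ((shift - cfg$peak_centers[k]) / cfg$peak_sigma_cm1)^2)
  }
  y
}

# Shell fluorescence day scaling (linear growth with storage).
fluorescence_day_scale <- function(cfg, day) {
  1 + cfg$fluorescence_growth_rate * (day - 1)
}

#' Generate single-layer reference backscatter spectra
#'
#' Produces the day-1 "meat" reference (a sum of Gaussian Raman peaks at the
#' configured centers on a low baseline) and the "shell" reference (a broad,
#' smooth fluorescence curve with no narrow peaks), both on the native
#' Raman-shift axis. These mirror the backscatter reference spectra an
#' operator would acquire at the laser point from each isolated layer, and
#' the meat reference drives anomalous-spectrum removal during
#' preprocessing.
#'
#' @param config A [sim_config()].
#' @return A list with elements `meat` and `shell`, each of class
#'   `sors_reference` with fields `layer`, `shift_cm1`, `intensity` and
#'   `typical_peaks` (cm^-1; empty for the shell).
#' @examples
#' refs <- generate_reference_spectra(sim_config())
#' refs$meat$typical_peaks
#' @export
generate_reference_spectra <- function(config) {
  stopifnot(inherits(config, "sors_sim_config"))
  shift <- native_shift_axis(config)
  meat <- structure(
    list(layer = "meat", shift_cm1 = shift,
         intensity = meat_spectrum(shift, config, day = 1),
         typical_peaks = config$peak_centers),
    class = "sors_reference")
  shell <- structure(
    list(layer = "shell", shift_cm1 = shift,
         intensity = shell_curve(shift),
         typical_peaks = numeric(0)),
    class = "sors_reference")
  list(meat = meat, shell = shell)
}

#' @export
print.sors_reference <- function(x, ...) {
  cat(sprintf("<sors_reference: %s> %d bands, %d typical peaks\n",
              x$layer, length(x$shift_cm1), length(x$typical_peaks)))
  invisible(x)
}

# Per-shrimp latent properties (constant across days): shell fluorescence
# scale jitter and the laser incidence pixel used for that shrimp.
shrimp_latents <- function(cfg, shrimp_id) {
  rs <- .Random.seed_swap(sample_seed(cfg, shrimp_id, day = 0L))
  on.exit(.Random.seed_restore(rs))
  lo <- max(2L, round(0.35 * cfg$n_pixels))
  hi <- min(cfg$n_pixels - 1L, round(0.65 * cfg$n_pixels))
  list(
    shell_scale = exp(rnorm(1, 0, cfg$shell_scale_jitter)),
    laser_index = if (hi > lo) sample(lo:hi, 1L) else lo
  )
}

# Localised RNG helpers: run a block under a private seed without
# disturbing the caller's RNG stream.
.Random.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate one raw scattering cube
#'
#' Builds the noiseless two-layer signal for every spatial pixel, then
#' replicates it over repeat scans and injects per-repeat artifacts. At
#' offset `d` mm from the laser pixel the signal is
#' `gain * (w_shell(d) * shell_scale * shell(shift) * g(day) +
#' w_meat(d) * meat(shift, day))`, with the exponential mixing kernel of
#' [sim_config()], linear fluorescence growth `g(day)` and geometric decay
#' of the protein peak amplitudes. Anomalous positions (drawn once per
#' sample) have their meat term replaced by a second shell-like curve.
#' Cosmic rays are isolated single-band spikes drawn per (repeat, pixel);
#' repeats otherwise differ only by additive Gaussian noise.
#'
#' @param shrimp_id Integer subject id in `1:n_shrimp`.
#' @param day Storage day in `1:n_days`.
#' @param config A [sim_config()].
#' @param seed Optional integer seed overriding the per-sample seed derived
#'   from `config$seed` (used for reproducibility tests).
#' @return A `sors_cube`: list with `data` (repeats x pixels x bands array),
#'   `wavelength_nm`, `laser_index`, `pixel_pitch_mm`, `shrimp_id`, `day`,
#'   and ground-truth artifact records `anomaly_pixels` (pixel indices) and
#'   `cosmic_rays` (tibble: repeat, pixel, band).
#' @export
simulate_sample <- function(shrimp_id, day, config, seed = NULL) {
  stopifnot(inherits(config, "sors_sim_config"))
  if (length(day) != 1L || is.na(day) || day < 1 || day > config$n_days) {
    abort(sprintf("`day` must lie in 1..%d", config$n_days),
          class = "sors_input_error")
  }
  if (shrimp_id < 1 || shrimp_id > config$n_shrimp) {
    abort(sprintf("`shrimp_id` must lie in 1..%d", config$n_shrimp),
          class = "sors_input_error")
  }
  lat <- shrimp_latents(config, shrimp_id)
  rs <- .Random.seed_swap(
    if (is.null(seed)) sample_seed(config, shrimp_id, day) else seed)
  on.exit(.Random.seed_restore(rs))

  shift <- native_shift_axis(config)
  nb <- config$native_band_count
  np <- config$n_pixels
  nr <- config$n_repeats
  pitch <- pixel_pitch_mm(config)

  d_mm <- abs(seq_len(np) - lat$laser_index) * pitch
  w <- mixing_weights(d_mm, config)
  gday <- fluorescence_day_scale(config, day)
  gain <- exp(rnorm(1, 0, config$gain_jitter))

  shell_spec <- lat$shell_scale * gday * shell_curve(shift)
  meat_spec <- meat_spectrum(shift, config, day)
  anom_spec <- gday * anomaly_curve(shift)

  anomalous <- runif(np) < config$anomaly_rate
  # pixels x bands noiseless image: shell term + (meat | anomalous shell-like)
  img <- outer(w$shell, shell_spec)
  img[!anomalous, ] <- img[!anomalous, , drop = FALSE] +
    outer(w$meat[!anomalous], meat_spec)
  img[anomalous, ] <- img[anomalous, , drop = FALSE] +
    outer(w$meat[anomalous], anom_spec)
  img <- gain * img

  # repeats differ only in noise and artifacts; build all repeats at once in
  # (pixel, band, repeat) layout where the signal broadcasts by recycling
  data <- if (config$noise_sd > 0) {
    array(rnorm(np * nb * nr, 0, config$noise_sd) + as.vector(img),
          dim = c(np, nb, nr))
  } else {
    array(as.vector(img), dim = c(np, nb, nr))
  }
  peak_signal <- max(img)
  cr <- list()
  for (r in seq_len(nr)) {
    hit <- which(runif(np) < config$cosmic_ray_rate)
    if (length(hit)) {
      bands <- sample.int(nb, length(hit), replace = TRUE)
      idx <- cbind(hit, bands, r)
      data[idx] <- data[idx] + runif(length(hit), 3, 6) * peak_signal
      cr[[length(cr) + 1L]] <- tibble(repeat_id = r, pixel = hit, band = bands)
    }
  }
  data <- aperm(data, c(3L, 1L, 2L))

  structure(
    list(
      data = data,
      wavelength_nm = shift_to_wavelength(shift, config$excitation_nm),
      excitation_nm = config$excitation_nm,
      laser_index = lat$laser_index,
      pixel_pitch_mm = pitch,
      shrimp_id = as.integer(shrimp_id),
      day = as.integer(day),
      anomaly_pixels = which(anomalous),
      cosmic_rays = if (length(cr)) dplyr::bind_rows(cr) else
        tibble(repeat_id = integer(), pixel = integer(), band = integer())
    ),
    class = "sors_cube")
}

#' @export
print.sors_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sors_cube> shrimp %d day %d: %d repeats x %d px x %d bands, laser @ px %d\n",
              x$shrimp_id, x$day, d[1], d[2], d[3], x$laser_index))
  invisible(x)
}

#' Enumerate the samples of a simulated campaign
#'
#' Deterministic metadata for a configured study: one row per
#' (shrimp, day) acquisition with its sample id and laser pixel. The
#' default design is 100 shrimp measured daily for 7 days, i.e. 700
#' samples.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sample_id`, `shrimp_id`, `day`,
#'   `laser_index`.
#' @examples
#' nrow(dataset_metadata(sim_config()))  # 700
#' @export
dataset_metadata <- function(config) {
  stopifnot(inherits(config, "sors_sim_config"))
  grid <- tidyr::expand_grid(shrimp_id = seq_len(config$n_shrimp),
                             day = seq_len(config$n_days))
  laser <- vapply(seq_len(config$n_shrimp),
                  function(s) shrimp_latents(config, s)$laser_index,
                  integer(1))
  dplyr::mutate(grid,
                sample_id = sprintf("S%03d_D%d", .data$shrimp_id, .data$day),
                laser_index = laser[.data$shrimp_id],
                .before = 1L) |>
    dplyr::select("sample_id", "shrimp_id", "day", "laser_index")
}

#' Generate a full synthetic dataset of raw scattering cubes
#'
#' Materialises every cube of the configured campaign as a list-column.
#' Memory scales as `n_shrimp * n_days * n_repeats * n_pixels * bands`
#' doubles; for full-size campaigns prefer the streaming
#' [preprocess_dataset()] which never holds more than one raw cube.
#'
#' @param config A [sim_config()].
#' @return A tibble: `sample_id`, `shrimp_id`, `day`, `laser_index`, and a
#'   list-column `cube` of `sors_cube` objects.
#' @export
generate_dataset <- function(config) {
  meta <- dataset_metadata(config)
  dplyr::mutate(meta, cube = purrr::map2(
    .data$shrimp_id, .data$day,
    function(s, d) simulate_sample(s, d, config)))
}
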