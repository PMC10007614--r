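#' Simulation configuration for synthetic SORS scattering cubes
#'
#' Describes a line-scan spatially offset Raman acquisition campaign on a
#' two-layer (shell over meat) sample set: the study design (shrimp x days),
#' the instrument geometry (spatial window, pixel count, excitation
#' wavelength, repeat scans), the spectral signal model (meat Raman peaks
#' with storage-day decay, shell fluorescence with storage-day growth,
#' offset-dependent surface/subsurface mixing) and the artifact model
#' (cosmic-ray spikes, anomalous shell positions, additive noise).
#'
#' The per-day evolution is geometric decay of the protein-related peak
#' amplitudes at 1148/1269/1311 cm^-1, amplitude times
#' `(1 - day_decay_rate)^(day - 1)`, and linear growth of the shell
#' fluorescence scale, `1 + fluorescence_growth_rate * (day - 1)`.
#' Surface/subsurface mixing at offset `d` mm uses an exponential kernel:
#' shell weight `w_s(d) = mix_floor + (mix_peak - mix_floor) *
#' exp(-|d| / surface_mixing_scale)` and meat weight `1 - w_s(d)`, so the
#' two weights always sum to one (full throughput normalisation).
#'
#' @param n_shrimp Number of subjects (default 100).
#' @param n_days Number of daily acquisitions per subject (default 7).
#' @param n_repeats Repeat line scans per sample (default 10).
#' @param n_pixels Spatial pixels per scan line (default 512).
#' @param window_mm Spatial window length imaged onto the pixels, mm
#'   (default 102.4, i.e. 0.2 mm pixel pitch).
#' @param excitation_nm Laser wavelength, nm (default 785).
#' @param native_band_count Number of native spectral bands uniformly
#'   covering `shift_range_cm1` (default 1000).
#' @param shift_range_cm1 Raman shift range covered by the native bands,
#'   cm^-1 (default c(600, 1800)).
#' @param peak_centers Meat Raman peak positions, cm^-1.
#' @param peak_amplitudes Peak amplitudes above the meat baseline, same
#'   length as `peak_centers`.
#' @param peak_sigma_cm1 Gaussian peak width (sd), cm^-1.
#' @param decaying_peaks Subset of `peak_centers` whose amplitude decays
#'   with storage day.
#' @param day_decay_rate Fractional amplitude decay per day for
#'   `decaying_peaks`, in \[0, 1).
#' @param fluorescence_growth_rate Per-day linear growth of the shell
#'   fluorescence scale.
#' @param surface_mixing_scale Exponential decay length (mm) of the shell
#'   contribution with offset distance.
#' @param mix_peak,mix_floor Shell mixing weight at zero offset and its
#'   large-offset asymptote; both in (0, 1), `mix_peak > mix_floor`.
#' @param shell_scale_jitter Lognormal sd of the per-shrimp shell
#'   fluorescence scale (between-sample shell variation).
#' @param gain_jitter Lognormal sd of the per-sample overall intensity gain
#'   (laser coupling / focus variation).
#' @param cosmic_ray_rate Probability of a cosmic-ray spike per
#'   (repeat, pixel).
#' @param anomaly_rate Probability that a spatial position is an anomalous
#'   shell region lacking meat peaks.
#' @param noise_sd Additive Gaussian noise sd per (repeat, pixel, band).
#' @param seed Integer seed; fully determines all generated data.
#'
#' @return A validated list of class `sors_sim_config`.
#' @examples
#' cfg <- sim_config(n_shrimp = 2, n_days = 3)
#' cfg$n_shrimp * cfg$n_days
#' @export
sim_config <- function(n_shrimp = 100,
                       n_days = 7,
                       n_repeats = 10,
                       n_pixels = 512,
                       window_mm = 102.4,
                       excitation_nm = 785,
                       native_band_count = 1000,
                       shift_range_cm1 = c(600, 1800),
                       peak_centers = c(1003, 1148, 1269, 1311, 1487),
                       peak_amplitudes = c(0.50, 0.45, 0.55, 0.50, 0.40),
                       peak_sigma_cm1 = 6,
                       decaying_peaks = c(1148, 1269, 1311),
                       day_decay_rate = 0.12,
                       fluorescence_growth_rate = 0.15,
                       surface_mixing_scale = 2,
                       mix_peak = 0.75,
                       mix_floor = 0.25,
                       shell_scale_jitter = 0.15,
                       gain_jitter = 0.25,
                       cosmic_ray_rate = 0.002,
                       anomaly_rate = 0.03,
                       noise_sd = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_shrimp = as.integer(n_shrimp), n_days = as.integer(n_days),
    n_repeats = as.integer(n_repeats), n_pixels = as.integer(n_pixels),
    window_mm = window_mm, excitation_nm = excitation_nm,
    native_band_count = as.integer(native_band_count),
    shift_range_cm1 = shift_range_cm1,
    peak_centers = peak_centers, peak_amplitudes = peak_amplitudes,
    peak_sigma_cm1 = peak_sigma_cm1, decaying_peaks = decaying_peaks,
    day_decay_rate = day_decay_rate,
    fluorescence_growth_rate = fluorescence_growth_rate,
    surface_mixing_scale = surface_mixing_scale,
    mix_peak = mix_peak, mix_floor = mix_floor,
    shell_scale_jitter = shell_scale_jitter, gain_jitter = gain_jitter,
    cosmic_ray_rate = cosmic_ray_rate, anomaly_rate = anomaly_rate,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sors_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_shrimp", "n_days", "n_repeats", "n_pixels",
              "native_band_count")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      abort(sprintf("`%s` must be a single count >= 1", f),
            class = "sors_config_error")
    }
  }
  rates <- c("cosmic_ray_rate", "anomaly_rate", "day_decay_rate",
             "fluorescence_growth_rate")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", f),
            class = "sors_config_error")
    }
  }
  if (cfg$noise_sd < 0 || cfg$shell_scale_jitter < 0 || cfg$gain_jitter < 0) {
    abort("noise/jitter scales must be nonnegative",
          class = "sors_config_error")
  }
  if (length(cfg$shift_range_cm1) != 2L ||
      diff(cfg$shift_range_cm1) <= 0) {
    abort("`shift_range_cm1` must be an increasing pair",
          class = "sors_config_error")
  }
  if (any(cfg$peak_centers < cfg$shift_range_cm1[1]) ||
      any(cfg$peak_centers > cfg$shift_range_cm1[2])) {
    abort("all `peak_centers` must lie inside `shift_range_cm1`",
          class = "sors_config_error")
  }
  if (length(cfg$peak_amplitudes) != length(cfg$peak_centers) ||
      any(cfg$peak_amplitudes < 0)) {
    abort("`peak_amplitudes` must be nonnegative, one per peak center",
          class = "sors_config_error")
  }
  if (!all(cfg$decaying_peaks %in% cfg$peak_centers)) {
    abort("`decaying_peaks` must be a subset of `peak_centers`",
          class = "sors_config_error")
  }
  # day-n_days amplitudes stay >= 0 for any rate < 1 (geometric decay)
  if (cfg$day_decay_rate >= 1) {
    abort("`day_decay_rate` must be < 1 so late-day amplitudes remain >= 0",
          class = "sors_config_error")
  }
  if (!(cfg$mix_floor > 0 && cfg$mix_peak < 1 &&
        cfg$mix_peak > cfg$mix_floor)) {
    abort("need 0 < mix_floor < mix_peak < 1", class = "sors_config_error")
  }
  if (cfg$surface_mixing_scale <= 0) {
    abort("`surface_mixing_scale` must be positive",
          class = "sors_config_error")
  }
  cfg
}

#' @export
print.sors_sim_config <- function(x, ...) {
  cat("<sors_sim_config>\n")
  cat(sprintf("  %d shrimp x %d days, %d repeats, %d px / %.1f mm, %d bands (%.0f-%.0f cm^-1)\n",
              x$n_shrimp, x$n_days, x$n_repeats, x$n_pixels, x$window_mm,
              x$native_band_count, x$shift_range_cm1[1], x$shift_range_cm1[2]))
  cat(sprintf("  excitation %g nm, seed %d\n", x$excitation_nm, x$seed))
  invisible(x)
}

# Spatial pixel pitch in mm.
pixel_pitch_mm <- function(cfg) cfg$window_mm / cfg$n_pixels

# Shell mixing weight at absolute offset d (mm); meat weight is 1 - w_shell
# so the layer weights always sum to 1 at every offset.
mixing_weights <- function(d_mm, cfg) {
  w_shell <- cfg$mix_floor +
    (cfg$mix_peak - cfg$mix_floor) * exp(-abs(d_mm) / cfg$surface_mixing_scale)
  list(shell = w_shell, meat = 1 - w_shell)
}
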