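# Preprocessing chain: raw scattering cube -> waveband x offset matrix.
# Stage order: crop_roi (with Stokes conversion) -> remove_anomalous_spectra
# -> remove_cosmic_rays -> average_and_smooth -> band_average -> fold_offsets.

#' Preprocessing configuration
#'
#' Parameters of the chain turning a raw scattering cube into the
#' waveband-by-offset matrix consumed by the models.
#'
#' @param roi_halfwidth_mm Half-width of the spatial region of interest on
#'   each side of the laser spot, mm (default 5, i.e. a 1 cm window).
#' @param shift_range_cm1 Raman-shift band of interest, cm^-1 (default
#'   c(600, 1800)).
#' @param sg_window Savitzky-Golay window length in bands (odd, default 11).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param n_bands_out Output waveband count after adjacent-band averaging
#'   (default 200; the native band count must be divisible by it).
#' @param n_offsets_out Output offset-bin count after symmetric folding
#'   (default 11, uniformly covering 0 to `roi_halfwidth_mm`).
#' @param peak_tolerance_cm1 Match window when comparing detected peaks to
#'   the reference typical peaks (default 10).
#' @param min_peaks_matched Minimum number of matched reference peaks for a
#'   spatial position to be kept (default 3).
#' @param peak_prominence Peak detection prominence threshold as a fraction
#'   of the spectrum's intensity range (default 0.02).
#' @param detrend_window_cm1 Running-median window (cm^-1) removed before
#'   peak detection so broad fluorescence humps are not reported as peaks
#'   (default 150).
#' @param normalize If `TRUE`, divide each processed matrix by its maximum
#'   (off by default; the models consume baseline-inclusive intensities).
#' @return A validated list of class `sors_preprocess_config`.
#' @export
preprocess_config <- function(roi_halfwidth_mm = 5,
                              shift_range_cm1 = c(600, 1800),
                              sg_window = 11,
                              sg_polyorder = 3,
                              n_bands_out = 200,
                              n_offsets_out = 11,
                              peak_tolerance_cm1 = 10,
                              min_peaks_matched = 3,
                              peak_prominence = 0.02,
                              detrend_window_cm1 = 150,
                              normalize = FALSE) {
  cfg <- list(roi_halfwidth_mm = roi_halfwidth_mm,
              shift_range_cm1 = shift_range_cm1,
              sg_window = as.integer(sg_window),
              sg_polyorder = as.integer(sg_polyorder),
              n_bands_out = as.integer(n_bands_out),
              n_offsets_out = as.integer(n_offsets_out),
              peak_tolerance_cm1 = peak_tolerance_cm1,
              min_peaks_matched = as.integer(min_peaks_matched),
              peak_prominence = peak_prominence,
              detrend_window_cm1 = detrend_window_cm1,
              normalize = isTRUE(normalize))
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_polyorder) {
    abort("`sg_window` must be odd and greater than `sg_polyorder`",
          class = "sors_config_error")
  }
  if (cfg$n_offsets_out < 2L) {
    abort("`n_offsets_out` must be >= 2", class = "sors_config_error")
  }
  if (cfg$peak_tolerance_cm1 <= 0) {
    abort("`peak_tolerance_cm1` must be positive",
          class = "sors_config_error")
  }
  if (cfg$roi_halfwidth_mm < 0) {
    abort("`roi_halfwidth_mm` must be nonnegative",
          class = "sors_config_error")
  }
  class(cfg) <- "sors_preprocess_config"
  cfg
}

#' Crop a cube to the spatial region of interest and band of interest
#'
#' Restricts the spatial axis to pixels within `roi_halfwidth_mm` of the
#' laser spot (pixel pitch = window / pixel count) and the spectral axis to
#' bands whose Raman shift (after Stokes conversion of the wavelength axis)
#' lies inside `shift_range_cm1`. With the default geometry (0.2 mm pitch,
#' 5 mm half-width) the ROI is 25 pixels each side plus the laser pixel:
#' 51 columns.
#'
#' @param cube A `sors_cube`.
#' @param config A [preprocess_config()].
#' @return The cropped `sors_cube`, carrying `shift_cm1` (converted axis),
#'   `laser_col` (index of the laser pixel inside the ROI),
#'   `pixel_offsets_mm` (signed per-column offsets) and an `excluded`
#'   logical mask (all `FALSE` until anomaly removal). Idempotent.
#' @export
crop_roi <- function(cube, config = preprocess_config()) {
  stopifnot(inherits(cube, "sors_cube"))
  if (isTRUE(cube$cropped)) return(cube)
  pitch <- cube$pixel_pitch_mm
  roi_px <- as.integer(round(config$roi_halfwidth_mm / pitch))
  np <- dim(cube$data)[2]
  if (cube$laser_index - roi_px < 1L || cube$laser_index + roi_px > np) {
    abort(sprintf(
      "ROI of %d px around laser pixel %d exceeds the %d-px window (shrimp %s day %s)",
      roi_px, cube$laser_index, np, cube$shrimp_id, cube$day),
      class = "sors_roi_error")
  }
  cols <- (cube$laser_index - roi_px):(cube$laser_index + roi_px)
  shift <- to_raman_shift(cube$wavelength_nm, cube$excitation_nm)
  tol <- 1e-6 * diff(config$shift_range_cm1)  # wavelength round-trip jitter
  keep_b <- which(shift >= config$shift_range_cm1[1] - tol &
                    shift <= config$shift_range_cm1[2] + tol)
  out <- cube
  out$data <- cube$data[, cols, keep_b, drop = FALSE]
  out$wavelength_nm <- cube$wavelength_nm[keep_b]
  out$shift_cm1 <- shift[keep_b]
  out$laser_col <- roi_px + 1L
  out$pixel_offsets_mm <- (cols - cube$laser_index) * pitch
  out$excluded <- rep(FALSE, length(cols))
  out$anomaly_pixels <- match(intersect(cube$anomaly_pixels, cols), cols)
  out$cropped <- TRUE
  out
}

#' Detect typical Raman peaks in a spectrum
#'
#' Removes a running-median trend (window `detrend_window_cm1`) so that
#' broad fluorescence structure is ignored, then reports local maxima of
#' the residual whose prominence is at least `peak_prominence` times the
#' intensity range of the original spectrum. A constant spectrum yields an
#' empty result.
#'
#' @param intensity Numeric intensity vector.
#' @param shift_cm1 Strictly increasing Raman-shift axis, same length.
#' @param config A [preprocess_config()].
#' @return Numeric vector of peak positions, cm^-1.
#' @export
detect_typical_peaks <- function(intensity, shift_cm1,
                                 config = preprocess_config()) {
  stopifnot(length(intensity) == length(shift_cm1))
  if (is.unsorted(shift_cm1, strictly = TRUE)) {
    abort("`shift_cm1` must be strictly increasing",
          class = "sors_input_error")
  }
  rng <- max(intensity) - min(intensity)
  if (rng <= 0) return(numeric(0))
  dx <- mean(diff(shift_cm1))
  k <- max(3L, round(config$detrend_window_cm1 / dx))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(intensity) - (1 - length(intensity) %% 2L))
  resid <- intensity - stats::runmed(intensity, k, endrule = "median")
  cand <- local_maxima(resid)
  if (!length(cand)) return(numeric(0))
  thr <- config$peak_prominence * rng
  # prominence never exceeds height above the global residual minimum
  cand <- cand[resid[cand] - min(resid) >= thr]
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) peak_prominence_at(resid, i), numeric(1))
  shift_cm1[cand[prom >= thr]]
}

# Interior local maxima, robust to flat plateaus (slopes are carried
# forward over zero-runs so an apex sampled at two equal points still
# registers as a sign change).
local_maxima <- function(y) {
  s <- sign(diff(y))
  nz <- cummax(seq_along(s) * (s != 0))
  nz[nz == 0] <- NA
  s <- s[nz]
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

# Topographic prominence of a local maximum: drop to the lowest point
# between the peak and the nearest higher ground on each side (or the
# boundary), take the larger of the two key saddles.
peak_prominence_at <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  higher <- which(left > h)
  lmin <- min(if (length(higher)) left[(max(higher) + 1L):(i - 1L)] else left,
              h)
  right <- y[(i + 1L):length(y)]
  higher <- which(right > h)
  rmin <- min(if (length(higher)) right[seq_len(min(higher) - 1L)] else right,
              h)
  h - max(lmin, rmin)
}

# Count how many reference peaks have a detected peak within tolerance.
match_reference_peaks <- function(detected, reference_peaks, tol) {
  if (!length(reference_peaks)) return(0L)
  sum(vapply(reference_peaks,
             function(p) length(detected) && min(abs(detected - p)) <= tol,
             logical(1)))
}

#' Flag and exclude anomalous shell positions
#'
#' Certain exoskeleton regions lack the typical Raman peaks of the meat
#' layer. Each spatial position's repeat-averaged spectrum is peak-matched
#' against the meat reference; positions matching fewer than
#' `min_peaks_matched` reference peaks (within `peak_tolerance_cm1`) are
#' excluded. Excluded positions contribute nothing to the later symmetric
#' fold — their mirror partner is used alone.
#'
#' @param cube A cropped `sors_cube` (see [crop_roi()]).
#' @param meat_reference A `sors_reference` for the meat layer with
#'   nonempty `typical_peaks`.
#' @param config A [preprocess_config()].
#' @return The cube with its `excluded` mask updated and
#'   `n_anomalies_removed` recorded.
#' @export
remove_anomalous_spectra <- function(cube, meat_reference,
                                     config = preprocess_config()) {
  stopifnot(inherits(cube, "sors_cube"), isTRUE(cube$cropped))
  if (!length(meat_reference$typical_peaks)) {
    abort("meat reference has no typical peaks", class = "sors_input_error")
  }
  # provisional repeat average, lightly smoothed so detector candidates are
  # real spectral features rather than residual noise maxima
  avg <- colMeans(cube$data)  # pixels x bands (mean over repeats)
  if (length(cube$shift_cm1) >= config$sg_window) {
    avg <- t(apply(avg, 1L, signal::sgolayfilt,
                   p = config$sg_polyorder, n = config$sg_window))
  }
  keep <- vapply(seq_len(nrow(avg)), function(p) {
    det <- detect_typical_peaks(avg[p, ], cube$shift_cm1, config)
    match_reference_peaks(det, meat_reference$typical_peaks,
                          config$peak_tolerance_cm1) >= config$min_peaks_matched
  }, logical(1))
  if (!any(keep)) {
    abort(sprintf("all spatial positions rejected as anomalous (shrimp %s day %s)",
                  cube$shrimp_id, cube$day),
          class = "sors_sample_rejected")
  }
  out <- cube
  out$excluded <- cube$excluded | !keep
  out$n_anomalies_removed <- sum(!keep)
  out
}

#' Trim cosmic-ray extremes across repeat scans
#'
#' Cosmic rays appear as abrupt single-band spikes in individual repeat
#' scans. For every (pixel, band) cell the maximum and minimum across the
#' repeat dimension are dropped, so downstream averaging is a trimmed mean
#' over the remaining repeats.
#'
#' @param cube A cropped `sors_cube` with at least 3 repeats.
#' @return The cube with per-cell trim statistics attached
#'   (`trim_stats`); its effective repeat count per cell is reduced by 2.
#' @export
remove_cosmic_rays <- function(cube) {
  stopifnot(inherits(cube, "sors_cube"))
  nr <- dim(cube$data)[1]
  if (nr < 3L) {
    abort("cosmic-ray trimming needs at least 3 repeats",
          class = "sors_input_error")
  }
  slices <- lapply(seq_len(nr), function(r) cube$data[r, , ])
  out <- cube
  out$trim_stats <- list(
    sum = Reduce(`+`, slices),
    max = Reduce(pmax, slices),
    min = Reduce(pmin, slices),
    n = nr)
  out
}

#' Trimmed mean of one repeat series
#'
#' The scalar operation applied per (pixel, band) cell by
#' [remove_cosmic_rays()] + averaging: drop one maximum and one minimum,
#' average the rest.
#'
#' @param x Numeric vector of repeat values (length >= 3).
#' @return The trimmed mean.
#' @export
trimmed_repeat_mean <- function(x) {
  if (length(x) < 3L) {
    abort("need at least 3 repeats", class = "sors_input_error")
  }
  (sum(x) - max(x) - min(x)) / (length(x) - 2L)
}

#' Average repeats and smooth along the spectral axis
#'
#' Computes the per-cell (trimmed) mean over repeats, then applies a
#' Savitzky-Golay filter (`sg_window`, `sg_polyorder`) along the band axis
#' of each spatial position.
#'
#' @param cube A cropped `sors_cube`, ideally after [remove_cosmic_rays()].
#' @param config A [preprocess_config()].
#' @return A `sors_image`: list with `intensity` (pixels x bands),
#'   `shift_cm1`, `laser_col`, `pixel_offsets_mm`, `excluded` and sample
#'   identity fields.
#' @export
average_and_smooth <- function(cube, config = preprocess_config()) {
  stopifnot(inherits(cube, "sors_cube"))
  nb <- length(cube$shift_cm1)
  if (nb < config$sg_window) {
    abort("fewer bands than the Savitzky-Golay window",
          class = "sors_config_error")
  }
  img <- if (!is.null(cube$trim_stats)) {
    with(cube$trim_stats, (sum - max - min) / (n - 2L))
  } else {
    colMeans(cube$data)
  }
  smooth <- t(apply(img, 1L, signal::sgolayfilt,
                    p = config$sg_polyorder, n = config$sg_window))
  structure(
    list(intensity = smooth, shift_cm1 = cube$shift_cm1,
         laser_col = cube$laser_col,
         pixel_offsets_mm = cube$pixel_offsets_mm,
         excluded = cube$excluded,
         shrimp_id = cube$shrimp_id, day = cube$day,
         n_anomalies_removed = cube$n_anomalies_removed %||% 0L),
    class = "sors_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average adjacent wavebands
#'
#' Reduces spectral redundancy by averaging non-overlapping blocks of
#' adjacent bands. The native band count must be divisible by
#' `n_bands_out`; with 1000 native bands and 200 output bands, blocks of 5.
#'
#' @param image A `sors_image`.
#' @param n_bands_out Output band count.
#' @return The image with `n_bands_out` bands and `band_centers_cm1` set to
#'   the block means of the input shift axis.
#' @export
band_average <- function(image, n_bands_out = 200L) {
  stopifnot(inherits(image, "sors_image"))
  nb <- length(image$shift_cm1)
  if (nb %% n_bands_out != 0L) {
    abort(sprintf(
      "native band count %d is not divisible by n_bands_out %d; adjust the spectral axis",
      nb, n_bands_out), class = "sors_config_error")
  }
  block <- nb %/% n_bands_out
  grp <- rep(seq_len(n_bands_out), each = block)
  B <- matrix(0, nb, n_bands_out)
  B[cbind(seq_len(nb), grp)] <- 1 / block
  out <- image
  out$intensity <- image$intensity %*% B
  out$band_centers_cm1 <- as.numeric(tapply(image$shift_cm1, grp, mean))
  out$shift_cm1 <- out$band_centers_cm1
  out
}

#' Fold symmetric offsets about the laser column and bin to output offsets
#'
#' Columns at +d and -d mm are averaged (a side excluded by anomaly removal
#' contributes nothing — the surviving partner is used alone), then the
#' folded distances are grouped into `n_offsets_out` uniform bins of width
#' `roi_halfwidth / (n_offsets_out - 1)` mm, averaging columns per bin.
#' With the default 51-column ROI this folds 26 distances (0 to 5 mm in
#' 0.2 mm steps) into 11 half-millimetre bins whose reported offsets are
#' 0, 0.5, ..., 5 mm.
#'
#' @param image A `sors_image` (after [band_average()] in the standard
#'   chain, though any band axis works).
#' @param n_offsets_out Number of output offset bins.
#' @return A `sors_processed`: list with `matrix` (bands x offsets),
#'   `band_centers_cm1`, `offsets_mm`, `day`, `shrimp_id`.
#' @export
fold_offsets <- function(image, n_offsets_out = 11L) {
  stopifnot(inherits(image, "sors_image"))
  np <- nrow(image$intensity)
  if (np %% 2L == 0L) {
    abort("ROI must have an odd number of columns (laser-centred)",
          class = "sors_geometry_error")
  }
  if (image$laser_col != (np + 1L) %/% 2L) {
    abort("laser column is not centred in the ROI",
          class = "sors_geometry_error")
  }
  half <- (np - 1L) %/% 2L
  d_mm <- abs(image$pixel_offsets_mm)
  X <- image$intensity
  X[image$excluded, ] <- NA_real_
  # fold: average column pairs at identical |d|, NA-aware
  folded <- vapply(0:half, function(k) {
    cols <- unique(c(image$laser_col - k, image$laser_col + k))
    colMeans(X[cols, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(X)))                      # bands x (half+1)
  fold_d <- d_mm[image$laser_col + 0:half]
  roi_half <- max(d_mm)
  width <- roi_half / (n_offsets_out - 1L)
  bin <- pmin(floor(fold_d / width) + 1L, n_offsets_out)
  mat <- vapply(seq_len(n_offsets_out), function(b) {
    cols <- which(bin == b)
    rowMeans(folded[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(folded)))
  if (any(!is.finite(mat))) {
    abort(sprintf("offset bin left empty after exclusions (shrimp %s day %s)",
                  image$shrimp_id, image$day),
          class = "sors_geometry_error")
  }
  structure(
    list(matrix = mat,
         band_centers_cm1 = image$band_centers_cm1 %||% image$shift_cm1,
         offsets_mm = (seq_len(n_offsets_out) - 1L) * width,
         day = image$day, shrimp_id = image$shrimp_id,
         n_anomalies_removed = image$n_anomalies_removed),
    class = "sors_processed")
}

#' @export
print.sors_processed <- function(x, ...) {
  cat(sprintf("<sors_processed> shrimp %s day %s: %d bands x %d offsets (%.0f-%.0f cm^-1, 0-%g mm)\n",
              x$shrimp_id, x$day, nrow(x$matrix), ncol(x$matrix),
              min(x$band_centers_cm1), max(x$band_centers_cm1),
              max(x$offsets_mm)))
  invisible(x)
}

#' Run the full preprocessing chain on one cube
#'
#' Applies, in order: [crop_roi()] (with Stokes shift conversion),
#' [remove_anomalous_spectra()], [remove_cosmic_rays()],
#' [average_and_smooth()], [band_average()] and [fold_offsets()]. Stage
#' failures are rethrown with the stage name and sample identity.
#'
#' @param cube A raw `sors_cube`.
#' @param meat_reference Meat-layer `sors_reference`.
#' @param config A [preprocess_config()].
#' @return A `sors_processed` with an `n_bands_out` x `n_offsets_out`
#'   matrix.
#' @export
preprocess_sample <- function(cube, meat_reference,
                              config = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("preprocess stage '%s' failed for shrimp %s day %s: %s",
                    name, cube$shrimp_id, cube$day, conditionMessage(e)),
            class = "sors_stage_error", parent = e)
    })
  }
  x <- stage("crop_roi", crop_roi(cube, config))
  x <- stage("remove_anomalous_spectra",
             remove_anomalous_spectra(x, meat_reference, config))
  x <- stage("remove_cosmic_rays", remove_cosmic_rays(x))
  x <- stage("average_and_smooth", average_and_smooth(x, config))
  x <- stage("band_average", band_average(x, config$n_bands_out))
  out <- stage("fold_offsets", fold_offsets(x, config$n_offsets_out))
  if (config$normalize) out$matrix <- out$matrix / max(out$matrix)
  out
}

#' Preprocess every cube of a materialised dataset
#'
#' @param dataset A tibble from [generate_dataset()] (list-column `cube`).
#' @param meat_reference Meat-layer `sors_reference`.
#' @param config A [preprocess_config()].
#' @return A tibble: `sample_id`, `shrimp_id`, `day`, `n_anomalies_removed`
#'   and list-column `spectra` of `sors_processed` objects.
#' @export
preprocess_dataset <- function(dataset, meat_reference,
                               config = preprocess_config()) {
  proc <- purrr::map(dataset$cube, preprocess_sample,
                     meat_reference = meat_reference, config = config)
  tibble(sample_id = dataset$sample_id,
         shrimp_id = dataset$shrimp_id,
         day = dataset$day,
         n_anomalies_removed =
           vapply(proc, function(p) p$n_anomalies_removed, numeric(1)),
         spectra = proc)
}

#' Simulate and preprocess a campaign without materialising raw cubes
#'
#' Streams the campaign sample by sample: each raw cube is generated,
#' preprocessed and discarded, so memory stays flat regardless of campaign
#' size.
#'
#' @param sim_cfg A [sim_config()].
#' @param pre_cfg A [preprocess_config()].
#' @return As [preprocess_dataset()].
#' @export
simulate_processed_dataset <- function(sim_cfg,
                                       pre_cfg = preprocess_config()) {
  refs <- generate_reference_spectra(sim_cfg)
  meta <- dataset_metadata(sim_cfg)
  proc <- purrr::map2(meta$shrimp_id, meta$day, function(s, d) {
    preprocess_sample(simulate_sample(s, d, sim_cfg), refs$meat, pre_cfg)
  })
  tibble(sample_id = meta$sample_id,
         shrimp_id = meta$shrimp_id,
         day = meta$day,
         n_anomalies_removed =
           vapply(proc, function(p) p$n_anomalies_removed, numeric(1)),
         spectra = proc)
}

#' Stack processed samples into a model input array
#'
#' @param processed A tibble with a `spectra` list-column of
#'   `sors_processed` objects sharing one geometry.
#' @return A numeric array `n x bands x offsets` with the storage-day
#'   labels as attribute `day`.
#' @export
as_model_input <- function(processed) {
  mats <- processed$spectra
  d <- dim(mats[[1]]$matrix)
  X <- array(0, dim = c(length(mats), d[1], d[2]))
  for (i in seq_along(mats)) X[i, , ] <- mats[[i]]$matrix
  attr(X, "day") <- processed$day
  X
}
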