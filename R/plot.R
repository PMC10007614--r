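# autoplot methods for the intermediate result types.

#' Heatmap of a processed waveband-by-offset matrix
#'
#' @param object A `sors_processed`.
#' @param ... Unused.
#' @return A ggplot raster of intensity over Raman shift and offset.
#' @export
autoplot.sors_processed <- function(object, ...) {
  df <- tidyr::expand_grid(shift = object$band_centers_cm1,
                           offset = object$offsets_mm)
  df$intensity <- as.vector(t(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$offset,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Raman shift (cm^-1)", y = "offset (mm)",
                  title = sprintf("shrimp %s, day %s",
                                  object$shrimp_id, object$day)) +
    ggplot2::theme_minimal()
}

#' Reference spectrum line plot
#'
#' @param object A `sors_reference`.
#' @param ... Unused.
#' @return A ggplot of intensity versus Raman shift with the typical
#'   peaks marked.
#' @export
autoplot.sors_reference <- function(object, ...) {
  df <- tibble(shift = object$shift_cm1, intensity = object$intensity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shift,
                                        y = .data$intensity)) +
    ggplot2::geom_line(colour = "#225ea8") +
    ggplot2::labs(x = "Raman shift (cm^-1)", y = "intensity",
                  title = sprintf("%s reference spectrum", object$layer)) +
    ggplot2::theme_minimal()
  if (length(object$typical_peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = object$typical_peaks,
                                 linetype = "dotted", colour = "grey50")
  }
  p
}
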