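# ggplot2 displays for spectra, peak analyses and band masks.

#' Plot a magnitude spectrum
#'
#' @param object A `pulse_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pulse_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Magnitude (a.u.)",
      title = attr(object, "provenance") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the peak-identification stages
#'
#' Faceted panels of the procedure: raw and smoothed spectra with the lower
#' envelope, then the adjusted spectrum with primary and final peaks
#' marked.
#'
#' @param object A `peak_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_analysis <- function(object, ...) {
  st <- object$stages
  long <- dplyr::bind_rows(
    tibble::tibble(frequency = st$frequency, value = st$raw,
                   curve = "raw", panel = "magnitude"),
    tibble::tibble(frequency = st$frequency, value = st$smoothed,
                   curve = "smoothed", panel = "magnitude"),
    tibble::tibble(frequency = st$frequency, value = st$envelope,
                   curve = "lower envelope", panel = "magnitude"),
    tibble::tibble(frequency = st$frequency, value = st$adjusted,
                   curve = "adjusted", panel = "adjusted")
  )
  long$panel <- factor(long$panel, levels = c("magnitude", "adjusted"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency, y = .data$value,
                                          colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.35) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL, colour = NULL,
                  title = object$provenance) +
    ggplot2::theme_minimal()
  if (nrow(object$peaks)) {
    pk <- dplyr::mutate(object$peaks, panel = factor("adjusted",
                                                     levels = levels(long$panel)))
    p <- p + ggplot2::geom_point(
      data = pk,
      ggplot2::aes(x = .data$frequency, y = .data$height),
      inherit.aes = FALSE, shape = 4, size = 2, stroke = 1
    )
  }
  p
}

#' Plot an axial montage of a band mask
#'
#' @param mask A `band_mask`.
#' @param slices Which z slices to show (default: every slice).
#' @return A ggplot object (tiles of mask voxels per slice).
#' @export
plot_band_mask <- function(mask, slices = NULL) {
  if (!inherits(mask, "band_mask")) abort("`mask` must be a band_mask.")
  d <- dim(mask$mask)
  if (is.null(slices)) slices <- seq_len(d[3])
  df <- purrr::map_dfr(slices, function(z) {
    idx <- which(mask$mask[, , z], arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble::tibble(x = idx[, 1], y = idx[, 2], z = z)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "firebrick") +
    ggplot2::facet_wrap(~z) +
    ggplot2::coord_fixed(xlim = c(1, d[1]), ylim = c(1, d[2])) +
    ggplot2::labs(
      title = sprintf("Band mask at %.3f Hz",
                      mask$band$center_frequency[[1]]),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}
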