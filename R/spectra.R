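# One-sided magnitude spectra of EPI voxel/ROI time series.
#
# Convention: amplitude-scaled one-sided FFT magnitude. After removing the
# temporal mean, magnitude(k) = (2/T) |DFT(k)| at interior bins and
# (1/T) |DFT(k)| at DC and (even T) Nyquist, so an on-grid sinusoid of
# amplitude A shows magnitude A at its bin. Power is derivable by squaring
# and is not stored.

#' Build the one-sided DFT frequency grid
#'
#' For `n_volumes` samples at repetition time `tr` the spectrum lives on
#' frequencies `k / (n_volumes * tr)` for `k = 0 .. floor(n_volumes/2)`:
#' resolution `1/(N*TR)` and maximum `1/(2*TR)` (the largest on-grid
#' frequency when `n_volumes` is odd). For 600 volumes at TR = 155 ms this
#' gives the familiar 0.011 Hz resolution and 3.226 Hz ceiling.
#'
#' @param n_volumes Number of time points (>= 2).
#' @param tr Sampling interval in seconds (> 0).
#' @return A list with `delta_f` (Hz), `f_max` (Hz) and the vector
#'   `frequencies`.
#' @examples
#' g <- make_frequency_grid(600, 0.155)
#' c(g$delta_f, g$f_max)
#' @export
make_frequency_grid <- function(n_volumes, tr) {
  if (!is.numeric(n_volumes) || length(n_volumes) != 1L || n_volumes < 2 ||
      n_volumes != round(n_volumes)) {
    abort("`n_volumes` must be a single integer >= 2.")
  }
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  n <- as.integer(n_volumes)
  delta_f <- 1 / (n * tr)
  k <- 0:(n %/% 2L)
  freqs <- k * delta_f
  list(delta_f = delta_f, f_max = freqs[length(freqs)], frequencies = freqs)
}

new_spectrum <- function(frequency, magnitude, n_samples, tr, provenance) {
  out <- tibble::tibble(frequency = frequency, magnitude = magnitude)
  class(out) <- c("pulse_spectrum", class(out))
  attr(out, "n_samples") <- n_samples
  attr(out, "tr") <- tr
  attr(out, "delta_f") <- 1 / (n_samples * tr)
  attr(out, "provenance") <- provenance
  out
}

# bins x V magnitude-spectrum matrix for a T x V matrix of series (columns).
spectral_matrix <- function(series_mat, tr) {
  n <- nrow(series_mat)
  nb <- n %/% 2L + 1L
  x <- sweep(series_mat, 2L, colMeans(series_mat))
  f <- mvfft(x)
  mag <- Mod(f[seq_len(nb), , drop = FALSE])
  scale <- rep(2 / n, nb)
  scale[1] <- 1 / n
  if (n %% 2L == 0L) scale[nb] <- 1 / n
  mag <- mag * scale
  mag[1, ] <- 0 # demeaned: DC is zero by construction
  mag
}

#' Magnitude spectrum of a single voxel time series
#'
#' Removes the temporal mean and returns the amplitude-scaled one-sided FFT
#' magnitude on the [make_frequency_grid()] of the series.
#'
#' @param series Numeric vector, the voxel time course (length >= 2, finite).
#' @param tr Sampling interval in seconds.
#' @param provenance Optional label describing where the series came from.
#' @return A `pulse_spectrum` tibble with columns `frequency` and
#'   `magnitude`, carrying `n_samples`, `tr` and `delta_f` as attributes.
#' @examples
#' t <- (0:99) * 0.1
#' sp <- voxel_spectrum(2 * sin(2 * pi * 0.5 * t), tr = 0.1)
#' sp[sp$magnitude > 1, ]
#' @export
voxel_spectrum <- function(series, tr, provenance = "voxel") {
  if (!is.numeric(series) || length(series) < 2L) {
    abort("`series` must be a numeric vector of length >= 2.")
  }
  if (anyNA(series) || !all(is.finite(series))) {
    abort("`series` contains non-finite values.")
  }
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  grid <- make_frequency_grid(length(series), tr)
  mag <- spectral_matrix(matrix(series, ncol = 1L), tr)[, 1]
  new_spectrum(grid$frequencies, mag, length(series), tr, provenance)
}

#' ROI-averaged magnitude spectrum
#'
#' Computes each masked voxel's magnitude spectrum and averages the
#' magnitudes per frequency (not the complex values), so coherent and
#' incoherent voxels contribute alike, as in per-region EPI pulsation
#' analysis.
#'
#' @param image An [as_image4d()] object.
#' @param mask Logical 3D array of the same spatial shape; at least one
#'   voxel must be selected.
#' @param provenance Label stored with the spectrum (e.g. region name).
#' @param chunk Number of voxels transformed per FFT block.
#' @return A `pulse_spectrum` tibble.
#' @export
roi_spectrum <- function(image, mask, provenance = "roi", chunk = 4096L) {
  if (!inherits(image, "image4d")) abort("`image` must be an image4d.")
  sp <- dim(image$data)[1:3]
  if (!is.array(mask) || !all(dim(mask) == sp)) {
    abort("`mask` must be a logical array matching the image's spatial shape.")
  }
  idx <- which(mask)
  if (!length(idx)) abort(sprintf("ROI '%s' selects no voxels.", provenance))
  n <- dim(image$data)[4]
  flat <- image$data
  dim(flat) <- c(prod(sp), n)
  nb <- n %/% 2L + 1L
  acc <- numeric(nb)
  for (block in split(idx, ceiling(seq_along(idx) / chunk))) {
    mags <- spectral_matrix(t(flat[block, , drop = FALSE]), image$tr)
    acc <- acc + rowSums(mags)
  }
  grid <- make_frequency_grid(n, image$tr)
  new_spectrum(grid$frequencies, acc / length(idx), n, image$tr, provenance)
}

#' Region-of-interest spectra for a labelled image
#'
#' One ROI-averaged spectrum per named region of the label scheme, plus a
#' `whole_brain` spectrum over all non-background voxels. Regions with no
#' voxels are omitted with a warning.
#'
#' @param image An [as_image4d()] object.
#' @param labels A [label_map()] aligned to `image`.
#' @return Named list of `pulse_spectrum` tibbles.
#' @export
region_spectra <- function(image, labels) {
  if (!inherits(labels, "label_map")) abort("`labels` must be a label_map.")
  sp <- dim(image$data)[1:3]
  if (!all(dim(labels$labels) == sp)) {
    abort("label map shape does not match the image.")
  }
  out <- list()
  wb <- labels$labels > 0
  if (!any(wb)) {
    warn("label map is all background; no region spectra computed.")
    return(out)
  }
  for (nm in names(labels$scheme)) {
    m <- labels$labels == labels$scheme[[nm]]
    if (!any(m)) {
      warn(sprintf("region '%s' has zero voxels; omitted.", nm))
      next
    }
    out[[nm]] <- roi_spectrum(image, m, provenance = nm)
  }
  out[["whole_brain"]] <- roi_spectrum(image, wb, provenance = "whole_brain")
  out
}

#' Bind a list of spectra into one long tibble
#'
#' @param spectra Named list of `pulse_spectrum` objects (e.g. from
#'   [region_spectra()]).
#' @return Tibble with columns `provenance`, `frequency`, `magnitude`.
#' @export
spectra_table <- function(spectra) {
  purrr::map_dfr(spectra, function(sp) {
    tibble::tibble(
      provenance = attr(sp, "provenance") %||% "spectrum",
      frequency = sp$frequency,
      magnitude = sp$magnitude
    )
  })
}

#' Export spectra as TSV
#'
#' Writes `frequency_hz`, `magnitude`, `provenance` columns.
#'
#' @inheritParams spectra_table
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_spectra <- function(spectra, path) {
  if (inherits(spectra, "pulse_spectrum")) spectra <- list(spectra)
  tab <- spectra_table(spectra)
  readr::write_tsv(
    dplyr::select(tab, frequency_hz = "frequency", magnitude = "magnitude",
                  provenance = "provenance"),
    path
  )
  invisible(path)
}

#' @export
print.pulse_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pulse_spectrum> %s: %d bins, delta_f = %.4g Hz, f_max = %.4g Hz\n",
    attr(x, "provenance") %||% "?", nrow(x),
    attr(x, "delta_f"), max(x$frequency)
  ))
  NextMethod()
}
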