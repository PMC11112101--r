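# broom-style accessors for the peak-analysis and pipeline objects.

#' Tidy a peak analysis into its final-peak table
#'
#' @param x A `peak_analysis` from [identify_peaks()].
#' @param ... Unused.
#' @return Tibble of final peaks (`frequency`, `height`, `prominence_db`)
#'   with the spectrum provenance attached.
#' @export
tidy.peak_analysis <- function(x, ...) {
  dplyr::mutate(x$peaks, provenance = x$provenance)
}

#' One-row summary of a peak analysis
#'
#' @param x A `peak_analysis`.
#' @param ... Unused.
#' @return One-row tibble: provenance, bin count, frequency resolution,
#'   number of primary and final peaks, baseline statistics.
#' @export
glance.peak_analysis <- function(x, ...) {
  tibble::tibble(
    provenance = x$provenance,
    n_bins = nrow(x$stages),
    delta_f = 1 / (x$n_samples * x$tr),
    n_primary_peaks = nrow(x$primary_peaks),
    n_final_peaks = nrow(x$peaks),
    baseline_mean = x$baseline$mean,
    baseline_sd = x$baseline$sd
  )
}

#' Tidy a pipeline result into its band table
#'
#' @param x A `pulse_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return The grouped band tibble across regions.
#' @export
tidy.pulse_pipeline <- function(x, ...) {
  x$bands
}

#' One-row-per-region summary of a pipeline result
#'
#' @param x A `pulse_pipeline`.
#' @param ... Unused.
#' @return Tibble with one row per analyzed region.
#' @export
glance.pulse_pipeline <- function(x, ...) {
  purrr::map_dfr(x$analyses, glance)
}
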