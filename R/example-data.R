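#' Bundled example band table
#'
#' Per-subject band biomarkers (centre frequency, peak magnitude, area,
#' 3 dB bandwidth) measured with this methodology in a whole-brain 7 T
#' ultrafast-EPI study of five adult volunteers, for the CSF, cortical
#' grey-matter, cerebral white-matter and whole-brain regions. The
#' `band_label` column carries the published cross-subject grouping
#' (Band 1 near 0.3 Hz respiratory, Band 4 near 1.2 Hz cardiac). Useful as
#' input to [summarize_bands()] and as a realistic worked example.
#'
#' @return Tibble with columns `region`, `subject`, `band_label`,
#'   `center_frequency`, `magnitude`, `area`, `bandwidth` (the band-table
#'   convention used throughout the package).
#' @examples
#' b <- example_band_table()
#' dplyr::count(b, region)
#' @export
example_band_table <- function() {
  path <- system.file("extdata", "example_bands.tsv", package = "csfpulse",
                      mustWork = TRUE)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out <- dplyr::rename(out, center_frequency = "frequency_hz",
                       magnitude = "magnitude_au", area = "area_hz",
                       bandwidth = "bandwidth_hz")
  out$band_label <- factor(out$band_label, levels = paste("Band", 1:4))
  out
}
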