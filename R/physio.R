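# Physiological traces (ECG, respiration belt): CSV round-trip, trigger
# alignment to the scan window, magnitude spectra, and band-overlap
# reporting against the image spectra.

#' Create a physiological trace
#'
#' @param samples Numeric vector of digitized values.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel `"ecg"` or `"respiration"` (free-form labels accepted).
#' @param trigger_time Seconds into the recording at which the scanner
#'   trigger fired (scan start).
#' @return A `physio_trace` tibble with columns `time` (s, from recording
#'   start) and `value`.
#' @export
physio_trace <- function(samples, sampling_rate, channel = "ecg",
                         trigger_time = 0) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    abort("`samples` must be a numeric vector (>= 2 samples).")
  }
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar_number(trigger_time, "trigger_time")
  dur <- length(samples) / sampling_rate
  if (trigger_time < 0 || trigger_time > dur) {
    abort(sprintf("trigger_time (%g s) outside the %g s recording.",
                  trigger_time, dur))
  }
  out <- tibble::tibble(
    time = (seq_along(samples) - 1) / sampling_rate,
    value = as.numeric(samples)
  )
  class(out) <- c("physio_trace", class(out))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "channel") <- channel
  attr(out, "trigger_time") <- trigger_time
  out
}

#' Write a physio trace to CSV
#'
#' Layout: a two-line metadata header (`sampling_rate_hz`, `channel`,
#' `trigger_time_s`), then a `sample` column with one value per line.
#'
#' @param trace A [physio_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physio_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sampling_rate_hz,channel,trigger_time_s", con)
  writeLines(sprintf("%.17g,%s,%.17g", attr(trace, "sampling_rate"),
                     attr(trace, "channel"), attr(trace, "trigger_time")), con)
  writeLines("sample", con)
  writeLines(sprintf("%.17g", trace$value), con)
  invisible(path)
}

#' Read a physio trace from CSV
#'
#' @param path Path written by [write_physio_csv()] (or matching its
#'   layout).
#' @return A [physio_trace()].
#' @export
read_physio_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || lines[1] != "sampling_rate_hz,channel,trigger_time_s") {
    abort(sprintf("'%s' is not a physio CSV (missing metadata header).", path))
  }
  meta <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  samples <- as.numeric(lines[-(1:3)])
  physio_trace(samples, sampling_rate = as.numeric(meta[1]), channel = meta[2],
               trigger_time = as.numeric(meta[3]))
}

#' Crop a physio trace to the scan window
#'
#' Uses the scanner trigger timestamp to cut the recording to
#' `[trigger_time, trigger_time + scan_duration]`, after which the trace is
#' directly comparable with the EPI time series.
#'
#' @param trace A [physio_trace()].
#' @param scan_duration Scan length in seconds (`n_volumes * tr`).
#' @return The cropped `physio_trace` (trigger_time reset to 0).
#' @export
align_to_scan <- function(trace, scan_duration) {
  stopifnot_scalar_number(scan_duration, "scan_duration", positive = TRUE)
  fs <- attr(trace, "sampling_rate")
  t0 <- attr(trace, "trigger_time")
  rec <- nrow(trace) / fs
  if (t0 + scan_duration > rec + 1e-9) {
    abort(sprintf(
      "scan window (%g s from trigger at %g s) exceeds the %g s recording.",
      scan_duration, t0, rec
    ))
  }
  start <- floor(t0 * fs) + 1L
  n <- round(scan_duration * fs)
  physio_trace(trace$value[start:(start + n - 1L)], sampling_rate = fs,
               channel = attr(trace, "channel"), trigger_time = 0)
}

#' Magnitude spectrum of a physio trace
#'
#' Demeaned one-sided magnitude spectrum on the trace's own grid
#' (`delta_f = 1/duration`), same convention as [voxel_spectrum()].
#'
#' @param trace A [physio_trace()].
#' @return A `pulse_spectrum` tibble with the channel as provenance.
#' @export
trace_spectrum <- function(trace) {
  voxel_spectrum(trace$value, tr = 1 / attr(trace, "sampling_rate"),
                 provenance = attr(trace, "channel"))
}

#' Frequency-band overlap between image and physio bands
#'
#' Crosses every image band with every physio band and reports interval
#' intersections: bands sharing no frequencies are omitted.
#' `overlap_fraction` is Jaccard on the intervals
#' (|intersection| / |union|).
#'
#' @param mri_bands Band tibble from the image analysis (`f_lo`, `f_hi`,
#'   `center_frequency`).
#' @param physio_bands Band tibble from trace analyses; a `channel` column
#'   is carried through when present.
#' @return Tibble with one row per overlapping pair: centre frequencies,
#'   overlap interval, `overlap_fraction`, `channel`.
#' @export
band_overlap <- function(mri_bands, physio_bands) {
  if (!nrow(mri_bands) || !nrow(physio_bands)) {
    return(tibble::tibble(
      mri_center = numeric(0), physio_center = numeric(0),
      overlap_lo = numeric(0), overlap_hi = numeric(0),
      overlap_fraction = numeric(0), channel = character(0)
    ))
  }
  pairs <- tidyr::expand_grid(i = seq_len(nrow(mri_bands)),
                              j = seq_len(nrow(physio_bands)))
  rows <- purrr::pmap_dfr(pairs, function(i, j) {
    a <- mri_bands[i, ]
    b <- physio_bands[j, ]
    lo <- max(a$f_lo, b$f_lo)
    hi <- min(a$f_hi, b$f_hi)
    if (hi <= lo) return(NULL)
    uni <- max(a$f_hi, b$f_hi) - min(a$f_lo, b$f_lo)
    tibble::tibble(
      mri_center = a$center_frequency,
      physio_center = b$center_frequency,
      overlap_lo = lo, overlap_hi = hi,
      overlap_fraction = (hi - lo) / uni,
      channel = if ("channel" %in% names(b)) b$channel else NA_character_
    )
  })
  rows
}
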