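# Band biomarkers: 3 dB bandwidth and area under the adjusted spectrum for
# each identified peak; grouping of bands across subjects; per-group
# mean / sample-standard-deviation summaries.

# Walk outward from peak bin i on curve y until it first drops below thr;
# stop early (truncated) at the grid edge or at the valley before strictly
# higher terrain (an adjacent taller peak). Returns crossing frequency,
# value there, and truncation flag.
band_edge <- function(y, freqs, i, thr, direction) {
  n <- length(y)
  h <- y[i]
  step <- if (direction == "left") -1L else 1L
  prev <- i
  j <- i + step
  while (j >= 1L && j <= n) {
    if (y[j] < thr) {
      # linear interpolation between prev and j
      f <- freqs[prev] + (freqs[j] - freqs[prev]) * (thr - y[prev]) / (y[j] - y[prev])
      return(list(f = f, v = thr, truncated = FALSE))
    }
    if (y[j] > h) {
      # rose into higher terrain: stop at the valley between
      seg <- if (direction == "left") j:i else i:j
      vi <- seg[which.min(y[seg])]
      return(list(f = freqs[vi], v = y[vi], truncated = TRUE))
    }
    prev <- j
    j <- j + step
  }
  edge <- if (direction == "left") 1L else n
  list(f = freqs[edge], v = y[edge], truncated = TRUE)
}

#' Band biomarkers for one identified peak
#'
#' The band is the interval around the peak where the adjusted spectrum
#' stays above `sqrt(2)/2` of the peak height (a 3 dB amplitude drop). Each
#' edge is located by linear interpolation at the first crossing; if the
#' curve reaches the grid edge or rises into a taller neighbouring peak
#' before crossing, the edge (or the intervening valley) is used and the
#' band is flagged `truncated`. The area is the trapezoidal integral of the
#' adjusted curve over the band (units Hz, the curve being dimensionless).
#'
#' @param analysis A `peak_analysis` from [identify_peaks()].
#' @param peak Row number into `analysis$peaks`, or a one-row tibble taken
#'   from it.
#' @return One-row tibble: `center_frequency`, `magnitude`, `f_lo`, `f_hi`,
#'   `bandwidth`, `area`, `truncated`.
#' @export
band_from_peak <- function(analysis, peak) {
  if (!inherits(analysis, "peak_analysis")) abort("`analysis` must be a peak_analysis.")
  if (is.numeric(peak) && length(peak) == 1L) {
    peak <- analysis$peaks[peak, ]
  }
  if (!nrow(peak)) abort("empty peak.")
  y <- analysis$stages$adjusted
  freqs <- analysis$stages$frequency
  i <- peak$index[[1]]
  if (is.na(i) || i < 1L || i > length(y) || freqs[i] != peak$frequency[[1]]) {
    abort("peak is not on this analysis' grid.")
  }
  h <- y[i]
  thr <- h * sqrt(2) / 2
  left <- band_edge(y, freqs, i, thr, "left")
  right <- band_edge(y, freqs, i, thr, "right")
  inside <- which(freqs > left$f & freqs < right$f)
  xs <- c(left$f, freqs[inside], right$f)
  ys <- c(left$v, y[inside], right$v)
  tibble::tibble(
    center_frequency = freqs[i],
    magnitude = h,
    f_lo = left$f,
    f_hi = right$f,
    bandwidth = right$f - left$f,
    area = trapz(xs, ys),
    truncated = left$truncated || right$truncated
  )
}

#' Bands for all final peaks of an analysis
#'
#' @inheritParams band_from_peak
#' @param region,subject Optional identifiers recorded with each band.
#' @return Tibble of [band_from_peak()] rows (possibly empty), with
#'   `region`/`subject` columns when supplied.
#' @export
bands_from_peaks <- function(analysis, region = NULL, subject = NULL) {
  if (!nrow(analysis$peaks)) {
    out <- tibble::tibble(
      center_frequency = numeric(0), magnitude = numeric(0),
      f_lo = numeric(0), f_hi = numeric(0), bandwidth = numeric(0),
      area = numeric(0), truncated = logical(0)
    )
  } else {
    out <- purrr::map_dfr(seq_len(nrow(analysis$peaks)),
                          function(k) band_from_peak(analysis, k))
  }
  if (!is.null(region)) out$region <- region
  if (!is.null(subject)) out$subject <- subject
  out
}

#' Group bands across subjects by centre frequency
#'
#' Single-linkage clustering in one dimension: sorted centre frequencies are
#' split wherever consecutive centres differ by more than `tolerance_hz`;
#' groups are labelled `Band 1`, `Band 2`, ... in increasing frequency
#' order. The 0.2 Hz default keeps the typical cross-subject spread of the
#' cardiac band (about 1.13-1.31 Hz) in one group while separating it from
#' sub-cardiac bands below about 0.92 Hz.
#'
#' @param bands Tibble with a `center_frequency` column (e.g. rows of
#'   [bands_from_peaks()] across subjects).
#' @param tolerance_hz Maximum gap between neighbouring centres within a
#'   group.
#' @return `bands` with a `band_label` factor column added, sorted by
#'   centre frequency.
#' @examples
#' group_bands(tibble::tibble(center_frequency = c(0.3, 1.2, 1.15)))
#' @export
group_bands <- function(bands, tolerance_hz = 0.2) {
  stopifnot_scalar_number(tolerance_hz, "tolerance_hz", positive = TRUE)
  if (!nrow(bands)) {
    bands$band_label <- factor(character(0))
    return(bands)
  }
  ord <- order(bands$center_frequency)
  centers <- bands$center_frequency[ord]
  grp <- cumsum(c(1, diff(centers) > tolerance_hz))
  labels <- paste("Band", grp)
  out <- bands[ord, ]
  out$band_label <- factor(labels, levels = unique(labels))
  out
}

#' Summarize band biomarkers across subjects
#'
#' Per band group (and region, when present): arithmetic mean and sample
#' (n-1) standard deviation of centre frequency, magnitude, area and
#' bandwidth. The standard deviation is `NA` for single-subject groups.
#' Values are kept at full precision; round only for presentation.
#'
#' @param bands Tibble with a `band_label` column (see [group_bands()]) and
#'   columns `center_frequency`, `magnitude`, `area`, `bandwidth`.
#' @return Tibble with one row per (region,) band group and
#'   `<metric>_mean` / `<metric>_sd` columns plus `n_subjects`.
#' @export
summarize_bands <- function(bands) {
  if (!"band_label" %in% names(bands)) {
    abort("`bands` must carry a `band_label` column; see group_bands().")
  }
  keys <- intersect(c("region", "band_label"), names(bands))
  sd_or_na <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
  bands |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      dplyr::across(
        dplyr::all_of(c("center_frequency", "magnitude", "area", "bandwidth")),
        list(mean = mean, sd = sd_or_na)
      ),
      .groups = "drop"
    )
}

#' Export a band table as TSV
#'
#' Columns mirror the biomarker table layout: region, subject, band label,
#' frequency, magnitude, area, bandwidth, truncated.
#'
#' @param bands Band tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bands <- function(bands, path) {
  cols <- c(region = "region", subject = "subject", band_label = "band_label",
            frequency_hz = "center_frequency", magnitude_au = "magnitude",
            area_hz = "area", bandwidth_hz = "bandwidth", truncated = "truncated")
  cols <- cols[cols %in% names(bands)]
  readr::write_tsv(dplyr::select(bands, dplyr::all_of(cols)), path)
  invisible(path)
}
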