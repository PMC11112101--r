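# Six-stage spectral peak identification: Savitzky-Golay smoothing, lower
# envelope, envelope-normalized ("adjusted") spectrum, primary peaks by a
# mean + std threshold, baseline statistics outside cardiac-width exclusion
# zones, and final peaks gated by the baseline threshold and a decibel
# prominence criterion.

#' Peak-identification parameters
#'
#' Defaults derive from normal adult physiology: the smoothing window spans
#' the normal respiratory range (12-20 breaths/min, i.e. `8/60` = 0.133 Hz)
#' and the exclusion zone spans the normal cardiac range (60-100 beats/min,
#' i.e. `40/60` = 0.667 Hz). For very short TR acquisitions (TR <= 75 ms)
#' the smoothing window sample count is doubled, reflecting the denser
#' frequency sampling of those spectra.
#'
#' @param sg_window_hz Savitzky-Golay window width in Hz.
#' @param sg_order Polynomial order of the smoother.
#' @param sg_window_multiplier Multiplier applied to the window sample
#'   count; `NULL` selects 2 when `tr <= 0.075` s, else 1.
#' @param exclusion_zone_hz Width in Hz of the zone placed around each
#'   primary peak when computing baseline statistics.
#' @param exclusion_half_width If `TRUE`, interpret `exclusion_zone_hz` as a
#'   half-width (zone of `2 * exclusion_zone_hz`); default is total width.
#' @param min_prominence_db Minimum topographic prominence in dB, measured
#'   on `20*log10(1 + adjusted)`, for a final peak.
#' @param tr Optional TR in seconds, used only to resolve
#'   `sg_window_multiplier` when that is `NULL`.
#' @return A `peak_params` list.
#' @examples
#' peak_params()$sg_window_hz * 60 # breaths-per-minute span
#' @export
peak_params <- function(sg_window_hz = (20 - 12) / 60,
                        sg_order = 2L,
                        sg_window_multiplier = NULL,
                        exclusion_zone_hz = (100 - 60) / 60,
                        exclusion_half_width = FALSE,
                        min_prominence_db = 1.5,
                        tr = NULL) {
  if (is.null(sg_window_multiplier)) {
    sg_window_multiplier <- if (!is.null(tr) && tr <= 0.075) 2 else 1
  }
  stopifnot_scalar_number(sg_window_hz, "sg_window_hz", positive = TRUE)
  stopifnot_scalar_number(exclusion_zone_hz, "exclusion_zone_hz", positive = TRUE)
  stopifnot_scalar_number(min_prominence_db, "min_prominence_db", positive = TRUE)
  stopifnot_scalar_number(sg_window_multiplier, "sg_window_multiplier", positive = TRUE)
  structure(
    list(
      sg_window_hz = sg_window_hz,
      sg_order = as.integer(sg_order),
      sg_window_multiplier = sg_window_multiplier,
      exclusion_zone_hz = exclusion_zone_hz,
      exclusion_half_width = isTRUE(exclusion_half_width),
      min_prominence_db = min_prominence_db
    ),
    class = "peak_params"
  )
}

sg_window_samples <- function(params, delta_f, n_bins) {
  w <- round(params$sg_window_hz * params$sg_window_multiplier / delta_f)
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, 5L)
  cap <- if (n_bins %% 2L == 0L) n_bins - 1L else n_bins
  w <- min(w, cap)
  if (w <= params$sg_order) abort("Spectrum too short for the smoothing window.")
  as.integer(w)
}

#' Savitzky-Golay smoothing of a magnitude spectrum
#'
#' Window length in samples is `round(sg_window_hz * multiplier / delta_f)`,
#' forced odd, with a minimum of 5 samples and capped (odd) at the spectrum
#' length. Edge bins are handled by evaluating the polynomial fitted over
#' the first/last full window.
#'
#' @param spectrum A `pulse_spectrum` tibble (>= 5 bins).
#' @param params A [peak_params()] list.
#' @return Numeric vector of smoothed magnitudes.
#' @export
smooth_spectrum <- function(spectrum, params = peak_params()) {
  y <- spectrum$magnitude
  if (length(y) < 5L) abort("Spectrum must have at least 5 bins.")
  delta_f <- attr(spectrum, "delta_f") %||% diff(spectrum$frequency[1:2])
  w <- sg_window_samples(params, delta_f, length(y))
  as.numeric(signal::sgolayfilt(y, p = params$sg_order, n = w))
}

#' Lower envelope of a smoothed spectrum
#'
#' Models the spectral floor characteristic of the acquisition: candidate
#' knots are the strict local minima of the smoothed curve (plus the first
#' post-DC bin and the last bin); minima sitting on the shoulders of peaks
#' -- i.e. lying above the straight line joining their neighbours -- are
#' pruned so the envelope bridges *under* each peak instead of climbing
#' onto it (the surviving knots form the lower convex hull of the minima).
#' The envelope interpolates linearly between knots, is clipped to never
#' exceed the curve, and floored at a tiny positive value so the
#' subsequent division is defined. The DC bin (zero after demeaning) is
#' excluded from envelope construction and inherits its neighbour's
#' value.
#'
#' @param smoothed Numeric vector of smoothed magnitudes.
#' @param frequencies Frequency grid of the same length.
#' @return Numeric vector, the envelope.
#' @export
lower_envelope <- function(smoothed, frequencies) {
  n <- length(smoothed)
  if (n < 2L) abort("Need at least 2 bins.")
  if (length(frequencies) != n) abort("frequency/magnitude length mismatch.")
  first <- if (n >= 3L) 2L else 1L
  cand <- sort(unique(c(first, strict_local_minima(smoothed), n)))
  cand <- cand[cand >= first]
  # lower convex hull (monotone chain) of the candidate knots: pop any
  # knot above the chord of its neighbours
  hull <- integer(0)
  for (i in cand) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      lhs <- (smoothed[b] - smoothed[a]) * (frequencies[i] - frequencies[a])
      rhs <- (smoothed[i] - smoothed[a]) * (frequencies[b] - frequencies[a])
      if (lhs >= rhs) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  env <- if (length(hull) >= 2L) {
    approx(frequencies[hull], smoothed[hull], xout = frequencies, rule = 2)$y
  } else {
    smoothed
  }
  if (first == 2L) env[1] <- env[2]
  env <- pmin(env, smoothed)
  top <- max(smoothed)
  if (top > 0) env <- pmax(env, 1e-12 * top)
  env
}

#' Envelope-normalize a smoothed spectrum
#'
#' `adjusted = smoothed / envelope - 1`: the relative elevation of the
#' spectrum above its acquisition floor, zero wherever the curve touches
#' the envelope.
#'
#' @param smoothed Smoothed magnitudes.
#' @param envelope Matching lower envelope (positive wherever `smoothed`
#'   is).
#' @return Numeric vector, the adjusted spectrum (>= 0).
#' @export
adjust_spectrum <- function(smoothed, envelope) {
  if (length(smoothed) != length(envelope)) abort("length mismatch.")
  if (any(envelope <= 0 & smoothed > 0)) {
    abort("internal error: non-positive envelope under positive spectrum.")
  }
  adj <- ifelse(envelope > 0, smoothed / envelope - 1, 0)
  pmax(adj, 0)
}

#' Primary (most evident) peaks of an adjusted spectrum
#'
#' Local maxima whose height reaches the mean plus one sample standard
#' deviation of the adjusted spectrum (DC bin excluded from both the
#' statistics and candidacy). Flat-topped runs count once, at their centre
#' bin.
#'
#' @param adjusted Adjusted-spectrum values.
#' @param frequencies Matching frequency grid.
#' @return Tibble with `index`, `frequency`, `height`.
#' @export
detect_primary_peaks <- function(adjusted, frequencies) {
  if (anyNA(adjusted)) abort("`adjusted` contains NA.")
  body <- adjusted[-1]
  thr <- mean(body) + sd(body)
  idx <- local_maxima(adjusted)
  idx <- idx[idx > 1L & adjusted[idx] >= thr]
  tibble::tibble(index = idx, frequency = frequencies[idx], height = adjusted[idx])
}

#' Baseline statistics outside peak exclusion zones
#'
#' Masks an interval of total width `exclusion_zone_hz` (or twice that, as a
#' half-width, when `exclusion_half_width`) around each primary peak and
#' returns the mean and sample standard deviation of the remaining
#' adjusted-spectrum bins (DC always excluded).
#'
#' @inheritParams detect_primary_peaks
#' @param primary_peaks Tibble from [detect_primary_peaks()].
#' @param params A [peak_params()] list.
#' @return List with `mean`, `sd`, and the logical `baseline_bins` mask.
#' @export
baseline_stats <- function(adjusted, frequencies, primary_peaks,
                           params = peak_params()) {
  half <- if (params$exclusion_half_width) params$exclusion_zone_hz else
    params$exclusion_zone_hz / 2
  keep <- rep(TRUE, length(adjusted))
  keep[1] <- FALSE
  for (f0 in primary_peaks$frequency) {
    keep[abs(frequencies - f0) <= half] <- FALSE
  }
  if (!any(keep)) {
    abort(paste(
      "Exclusion zones cover the entire spectrum; widen the analyzed band",
      "or reduce the number of primary peaks."
    ))
  }
  vals <- adjusted[keep]
  s <- if (length(vals) >= 2L) sd(vals) else 0
  list(mean = mean(vals), sd = s, baseline_bins = keep)
}

#' Final peaks: baseline threshold plus prominence gate
#'
#' Local maxima of the adjusted spectrum whose height reaches
#' `baseline mean + baseline sd` and whose topographic prominence on the
#' decibel ratio curve `20*log10(1 + adjusted)` reaches
#' `min_prominence_db`. Returned sorted by frequency.
#'
#' @inheritParams baseline_stats
#' @param baseline List from [baseline_stats()].
#' @return Tibble with `index`, `frequency`, `height`, `prominence_db`.
#' @export
detect_final_peaks <- function(adjusted, frequencies, baseline,
                               params = peak_params()) {
  thr <- baseline$mean + baseline$sd
  idx <- local_maxima(adjusted)
  idx <- idx[idx > 1L & adjusted[idx] >= thr]
  db <- 20 * log10(1 + adjusted)
  prom <- peak_prominences(db, idx)
  keep <- prom >= params$min_prominence_db
  tibble::tibble(
    index = idx[keep],
    frequency = frequencies[idx[keep]],
    height = adjusted[idx[keep]],
    prominence_db = prom[keep]
  )
}

#' Identify spectral peaks (full six-stage procedure)
#'
#' Composes [smooth_spectrum()], [lower_envelope()], [adjust_spectrum()],
#' [detect_primary_peaks()], [baseline_stats()] and [detect_final_peaks()]
#' into the complete peak-identification procedure. Deterministic for fixed
#' input.
#'
#' @param spectrum A `pulse_spectrum` tibble.
#' @param params A [peak_params()] list; when built with default
#'   `sg_window_multiplier = NULL` the multiplier resolves from the
#'   spectrum's own TR.
#' @return A `peak_analysis` object: a list with `stages` (tibble of
#'   `frequency`, `raw`, `smoothed`, `envelope`, `adjusted`), `peaks`
#'   (final peaks tibble), `primary_peaks`, `baseline`, `params`, and the
#'   spectrum's provenance. Use [tidy()] for the peaks, [glance()] for a
#'   one-row summary, [autoplot()] for the stage panels.
#' @examples
#' t <- (0:299) * 0.155
#' sp <- voxel_spectrum(100 + 3 * sin(2 * pi * 1.2 * t) + rnorm(300, 0, 0.2),
#'                      tr = 0.155)
#' identify_peaks(sp)$peaks
#' @export
identify_peaks <- function(spectrum, params = NULL) {
  if (!inherits(spectrum, "pulse_spectrum")) {
    abort("`spectrum` must be a pulse_spectrum (see voxel_spectrum()).")
  }
  if (is.null(params)) params <- peak_params(tr = attr(spectrum, "tr"))
  # magnitudes are non-negative; clamp any smoothing undershoot before the
  # envelope stage so the floor model stays physical
  smoothed <- pmax(smooth_spectrum(spectrum, params), 0)
  envelope <- lower_envelope(smoothed, spectrum$frequency)
  adjusted <- adjust_spectrum(smoothed, envelope)
  primary <- detect_primary_peaks(adjusted, spectrum$frequency)
  baseline <- baseline_stats(adjusted, spectrum$frequency, primary, params)
  peaks <- detect_final_peaks(adjusted, spectrum$frequency, baseline, params)
  structure(
    list(
      stages = tibble::tibble(
        frequency = spectrum$frequency,
        raw = spectrum$magnitude,
        smoothed = smoothed,
        envelope = envelope,
        adjusted = adjusted
      ),
      peaks = peaks,
      primary_peaks = primary,
      baseline = baseline[c("mean", "sd")],
      params = params,
      provenance = attr(spectrum, "provenance") %||% "spectrum",
      tr = attr(spectrum, "tr"),
      n_samples = attr(spectrum, "n_samples")
    ),
    class = "peak_analysis"
  )
}

#' @export
print.peak_analysis <- function(x, ...) {
  cat(sprintf("<peak_analysis> %s: %d final peak(s)\n", x$provenance, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    print(x$peaks)
  }
  invisible(x)
}
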