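# Seeded synthetic phantom: a 4D EPI-like dataset with a CSF ellipsoid,
# cortical grey-matter shell and white-matter interior, region-dependent
# pulsatile sinusoids (respiratory ~0.3 Hz, cardiac ~1.2 Hz, harmonic
# ~2.4 Hz), slow drift, a 1/f acquisition-like spectral floor, and Rician
# magnitude noise -- everything with known ground truth.

#' Specify a synthetic pulsation phantom
#'
#' Defaults describe a whole-slab acquisition-like dataset: 64 x 64 x 20
#' voxels, 600 volumes at TR 0.155 s. Geometry is given as semi-axis
#' fractions of the grid so the same spec scales to smaller grids. Component
#' amplitudes are fractions of the regional baseline signal; CSF pulses
#' strongest, then cortical grey matter, then white matter. Component
#' frequencies are snapped to the DFT grid by default so the generated
#' amplitudes land in single bins.
#'
#' @param shape Integer length-4: X, Y, Z, T.
#' @param tr Repetition time in seconds.
#' @param components Tibble with columns `name`, `frequency` (Hz) and
#'   per-region amplitude fractions `csf`, `cgm`, `cwm`.
#' @param geometry List of semi-axis fractions (of each grid dimension) for
#'   the head ellipsoid, the white-matter interior and the CSF core.
#' @param baseline Named baseline intensities (a.u.) per region.
#' @param baseline_cv Per-voxel coefficient of variation of the baseline.
#' @param drift_slope Named linear drift (a.u./s) per region.
#' @param line_width_hz Slow physiological rate drift: each component's
#'   instantaneous frequency sweeps smoothly and monotonically across
#'   `f +/- 2*line_width_hz` over the scan, with a dwell-time density
#'   shaped as a truncated Lorentzian of half-width `line_width_hz`, so
#'   each spectral line becomes a smooth bell a few bins wide (heart and
#'   breathing rates drift a few percent over a minute-scale scan;
#'   perfectly monochromatic lines are unphysical). Set to 0 for pure
#'   sinusoids.
#' @param rician_sigma Gaussian channel noise std in the Rician magnitude
#'   model (a.u.).
#' @param envelope_exponent Spectral slope alpha of the added coloured
#'   noise (power ~ 1/f^alpha), producing the decreasing lower envelope.
#' @param colored_frac Amplitude of the coloured floor at 1 Hz as a
#'   fraction of the regional baseline intensity (signal-dependent
#'   physiological/acquisition fluctuations; one-sided magnitude-spectrum
#'   units). Background voxels carry no coloured floor, only channel
#'   noise.
#' @param snap_to_grid Snap component frequencies to the DFT grid.
#' @param seed Integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 20L, 600L),
                         tr = 0.155,
                         components = tibble::tibble(
                           name = c("respiratory", "cardiac", "harmonic"),
                           frequency = c(0.3, 1.2, 2.4),
                           csf = c(0.015, 0.03, 0.01),
                           cgm = c(0.008, 0.01, 0.01 / 3),
                           cwm = c(0.004, 0.004, 0.004 / 3)
                         ),
                         geometry = list(
                           head = c(0.44, 0.44, 0.48),
                           wm = c(0.34, 0.34, 0.38),
                           csf = c(0.14, 0.11, 0.20)
                         ),
                         baseline = c(csf = 500, cgm = 450, cwm = 400),
                         baseline_cv = 0.02,
                         drift_slope = c(csf = 0.02, cgm = 0.02, cwm = 0.02),
                         line_width_hz = 0.025,
                         rician_sigma = 2,
                         envelope_exponent = 1,
                         colored_frac = 0.0015,
                         snap_to_grid = TRUE,
                         seed = 1L) {
  if (length(shape) != 4L || any(shape < 2)) abort("`shape` must be X,Y,Z,T (all >= 2).")
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  nyq <- 1 / (2 * tr)
  if (any(components$frequency >= nyq)) {
    abort(sprintf("component frequencies must be below Nyquist (%.3f Hz).", nyq))
  }
  if (any(c(components$csf, components$cgm, components$cwm) < 0)) {
    abort("amplitude fractions must be >= 0.")
  }
  if (rician_sigma < 0) abort("`rician_sigma` must be >= 0.")
  structure(
    list(shape = as.integer(shape), tr = tr, components = components,
         geometry = geometry, baseline = baseline, baseline_cv = baseline_cv,
         drift_slope = drift_slope, line_width_hz = line_width_hz,
         rician_sigma = rician_sigma,
         envelope_exponent = envelope_exponent,
         colored_frac = colored_frac,
         snap_to_grid = isTRUE(snap_to_grid), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Ellipsoid-based segmentation: 1 = csf core, 2 = cgm shell, 3 = cwm
# interior, 0 = outside the head.
phantom_labels <- function(shape, geometry) {
  d <- shape[1:3]
  ctr <- (d + 1) / 2
  ax <- function(frac) pmax(frac * d, 1e-6)
  inside <- function(semi) {
    x <- (seq_len(d[1]) - ctr[1]) / semi[1]
    y <- (seq_len(d[2]) - ctr[2]) / semi[2]
    z <- (seq_len(d[3]) - ctr[3]) / semi[3]
    outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  }
  head <- inside(ax(geometry$head))
  wm <- inside(ax(geometry$wm))
  csf <- inside(ax(geometry$csf))
  lab <- array(0L, dim = d)
  lab[head] <- 2L            # grey-matter shell
  lab[wm] <- 3L              # white-matter interior
  lab[csf] <- 1L             # CSF core
  lab
}

# Coloured (1/f^alpha power) noise, synthesized in the frequency domain with
# deterministic per-bin amplitude and uniform random phase; returns an
# n_voxels x T matrix.
colored_noise_matrix <- function(n_voxels, n_time, tr, amplitude, alpha) {
  if (amplitude <= 0) return(matrix(0, n_voxels, n_time))
  nb <- n_time %/% 2L
  fk <- (1:nb) / (n_time * tr)
  A <- amplitude * fk^(-alpha / 2)
  theta <- matrix(runif(nb * n_voxels, 0, 2 * pi), nrow = nb)
  spec <- matrix(0 + 0i, n_time, n_voxels)
  spec[2:(nb + 1L), ] <- (n_time / 2) * A * exp(1i * theta)
  if (n_time %% 2L == 0L) {
    # Nyquist coefficient must be real; random sign keeps its magnitude
    spec[nb + 1L, ] <- n_time * A[nb] * sign(cos(theta[nb, ]))
  }
  conj_rows <- n_time - (1:nb) + 1L
  keep <- conj_rows > nb + 1L
  spec[conj_rows[keep], ] <- Conj(spec[(2:(nb + 1L))[keep], ])
  t(Re(mvfft(spec, inverse = TRUE)) / n_time)
}

#' Generate a synthetic phantom dataset
#'
#' Noiseless signal per voxel v in region r:
#' `S_v(t) = B_v * (1 + sum_k a_kr * sin(theta_k(t) + phi_k)) + d_r * t`,
#' where `theta_k` is the phase of a slow smooth rate sweep centred on
#' `f_k` (see `line_width_hz`; zero width recovers pure sinusoids), plus
#' a
#' coloured-noise term with `1/f^alpha` power spectrum; the observed value
#' is the Rician magnitude `sqrt((S + e1)^2 + e2^2)` with independent
#' Gaussian `e1, e2` of std `rician_sigma`. Deterministic under a fixed
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([as_image4d()]), `labels` ([label_map()]) and
#'   `truth` (component frequencies actually used, per-region amplitudes,
#'   region masks, phases, and the spec).
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(8, 8, 4, 64), seed = 7))
#' ph$truth$frequencies
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  set.seed(spec$seed)
  d <- spec$shape
  nt <- d[4]
  nv <- prod(d[1:3])
  tvec <- (0:(nt - 1)) * spec$tr
  grid <- make_frequency_grid(nt, spec$tr)
  freqs <- spec$components$frequency
  if (spec$snap_to_grid) {
    freqs <- pmax(1L, round(freqs / grid$delta_f)) * grid$delta_f
  }
  phases <- runif(length(freqs), 0, 2 * pi)
  # slow smooth rate drift, coherent across the brain: the instantaneous
  # frequency sweeps f + gamma*tan(u), u linear over +/- atan(2), whose
  # dwell-time density is a truncated Lorentzian of half-width gamma
  total_t <- nt * spec$tr
  gam <- spec$line_width_hz
  u0 <- atan(2)
  comp_phase <- function(k) {
    if (gam > 0) {
      u <- u0 * (2 * tvec / total_t - 1)
      2 * pi * (freqs[k] * tvec +
                  gam * total_t / (2 * u0) * (-log(cos(u)))) + phases[k]
    } else {
      2 * pi * freqs[k] * tvec + phases[k]
    }
  }
  lab <- phantom_labels(d, spec$geometry)
  mat <- matrix(0, nv, nt)
  region_codes <- c(csf = 1L, cgm = 2L, cwm = 3L)
  for (r in names(region_codes)) {
    idx <- which(lab == region_codes[[r]])
    if (!length(idx)) next
    amps <- spec$components[[r]]
    course <- 1 + rowSums(vapply(seq_along(freqs), function(k) {
      amps[k] * sin(comp_phase(k))
    }, numeric(nt)))
    base <- spec$baseline[[r]] * (1 + rnorm(length(idx), 0, spec$baseline_cv))
    mat[idx, ] <- outer(base, course) +
      matrix(spec$drift_slope[[r]] * tvec, length(idx), nt, byrow = TRUE)
    # signal-proportional coloured floor (physiological/acquisition
    # fluctuations scale with tissue intensity)
    if (spec$colored_frac > 0) {
      amp <- spec$colored_frac * spec$baseline[[r]]
      chunk <- 4096L
      for (block in split(idx, ceiling(seq_along(idx) / chunk))) {
        mat[block, ] <- mat[block, ] + colored_noise_matrix(
          length(block), nt, spec$tr, amp, spec$envelope_exponent
        )
      }
    }
  }
  # Rician magnitude observation, chunked to bound temporary allocations
  if (spec$rician_sigma > 0) {
    cols <- split(seq_len(nt), ceiling(seq_len(nt) / 100L))
    for (cc in cols) {
      e1 <- matrix(rnorm(nv * length(cc), 0, spec$rician_sigma), nv)
      e2 <- matrix(rnorm(nv * length(cc), 0, spec$rician_sigma), nv)
      mat[, cc] <- sqrt((mat[, cc] + e1)^2 + e2^2)
    }
  } else {
    mat <- abs(mat)
  }
  dim(mat) <- d
  image <- as_image4d(mat, tr = spec$tr)
  labels <- label_map(lab)
  amp_tab <- spec$components
  amp_tab$frequency <- freqs
  truth <- list(
    frequencies = setNames(freqs, spec$components$name),
    phases = phases,
    amplitudes = amp_tab,
    masks = list(csf = lab == 1L, cgm = lab == 2L, cwm = lab == 3L),
    delta_f = grid$delta_f,
    spec = spec
  )
  list(image = image, labels = labels, truth = truth)
}

#' Generate matched synthetic physiological traces
#'
#' Produces a respiration-belt-like sinusoid at the phantom's respiratory
#' frequency and an ECG-like train of narrow Gaussian pulses at its cardiac
#' frequency, both seeded from the spec, sampled at `sampling_rate`, with
#' the scan starting `trigger_time` seconds into the recording.
#'
#' @param spec A [phantom_spec()]; its respiratory/cardiac frequencies (as
#'   snapped to the image grid) drive the traces.
#' @param sampling_rate Digitization rate in Hz (default 250).
#' @param trigger_time Scan start within the recording (s).
#' @param tail_s Extra recording after the scan ends (s).
#' @param noise_sd Additive Gaussian noise std on both channels.
#' @return List with `ecg` and `respiration` [physio_trace()] objects.
#' @export
make_physio_traces <- function(spec, sampling_rate = 250, trigger_time = 10,
                               tail_s = 5, noise_sd = 0.05) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  grid <- make_frequency_grid(spec$shape[4], spec$tr)
  freqs <- spec$components$frequency
  if (spec$snap_to_grid) freqs <- pmax(1L, round(freqs / grid$delta_f)) * grid$delta_f
  f_resp <- freqs[match("respiratory", spec$components$name)]
  f_card <- freqs[match("cardiac", spec$components$name)]
  if (sampling_rate <= 2 * max(f_resp, f_card)) {
    abort("sampling_rate must exceed twice the fastest component.")
  }
  set.seed(spec$seed + 10000L)
  dur <- trigger_time + spec$shape[4] * spec$tr + tail_s
  t <- seq(0, dur, by = 1 / sampling_rate)
  resp <- sin(2 * pi * f_resp * t) + rnorm(length(t), 0, noise_sd)
  # ECG: narrow Gaussian pulse at each beat
  period <- 1 / f_card
  beats <- seq(0, dur, by = period)
  ecg <- rnorm(length(t), 0, noise_sd / 2)
  w <- 0.02
  for (b in beats) {
    sel <- which(abs(t - b) <= 4 * w)
    ecg[sel] <- ecg[sel] + exp(-(t[sel] - b)^2 / (2 * w^2))
  }
  list(
    ecg = physio_trace(ecg, sampling_rate, channel = "ecg",
                       trigger_time = trigger_time),
    respiration = physio_trace(resp, sampling_rate, channel = "respiration",
                               trigger_time = trigger_time)
  )
}
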