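# Six-stage peak identification: smoothing, envelope, adjustment,
# thresholds, prominence.

test_that("default parameters derive from physiological ranges", {
  p <- peak_params()
  expect_equal(round(p$sg_window_hz, 3), 0.133)   # 12-20 breaths/min span
  expect_equal(p$sg_window_hz, (20 - 12) / 60)
  expect_equal(round(p$exclusion_zone_hz, 3), 0.667) # 60-100 beats/min span
  expect_equal(p$exclusion_zone_hz, (100 - 60) / 60)
  expect_equal(p$sg_order, 2L)
  expect_equal(p$min_prominence_db, 1.5)
  # short-TR acquisitions double the window sample count
  expect_equal(peak_params(tr = 0.051)$sg_window_multiplier, 2)
  expect_equal(peak_params(tr = 0.155)$sg_window_multiplier, 1)
})

test_that("smoothing reproduces quadratics exactly and matches the sliding-fit oracle", {
  freqs <- (0:100) * 0.01
  quad <- 2 + 3 * freqs + 5 * freqs^2
  sp <- csfpulse:::new_spectrum(freqs, quad, 202, 0.495, "quad")
  expect_equal(smooth_spectrum(sp), quad, tolerance = 1e-9)
  # constant input unchanged
  spc <- csfpulse:::new_spectrum(freqs, rep(4, 101), 202, 0.495, "const")
  expect_equal(smooth_spectrum(spc), rep(4, 101), tolerance = 1e-12)
  # seeded noise: equals the naive per-window polynomial fit
  set.seed(99)
  noisy <- abs(rnorm(101, 1, 0.3))
  spn <- csfpulse:::new_spectrum(freqs, noisy, 202, 0.495, "noise")
  p <- peak_params()
  w <- csfpulse:::sg_window_samples(p, 0.01, 101)
  expect_equal(smooth_spectrum(spn, p), naive_sgolay(noisy, w),
               tolerance = 1e-9)
  expect_error(
    smooth_spectrum(csfpulse:::new_spectrum(freqs[1:3], noisy[1:3], 6, 16.8, "x")),
    "5 bins"
  )
})

test_that("lower envelope is linear between knots and never exceeds the curve", {
  freqs <- (0:60) * 0.05
  # constant: envelope equals the curve
  expect_equal(lower_envelope(rep(2, 61), freqs), rep(2, 61))
  # V-shape: envelope equals the curve away from the excluded DC bin
  v <- c(abs(seq(-3, 3, length.out = 61))) + 1
  env_v <- lower_envelope(v, freqs)
  expect_equal(env_v[-1], v[-1], tolerance = 1e-12)
  # two bumps over a sloped floor: bridge under each bump
  floor_c <- 2 - 0.02 * freqs
  bump <- function(f0, h, w) h * exp(-(freqs - f0)^2 / (2 * w^2))
  y <- floor_c + bump(1, 1.5, 0.1) + bump(2.2, 1, 0.1)
  env <- lower_envelope(y, freqs)
  expect_true(all(env <= y + 1e-12))
  expect_true(all(env > 0))
  # under each bump the envelope stays near the floor, not the bump
  expect_lt(env[which.max(y)], floor_c[which.max(y)] + 0.1)
  # piecewise linearity between consecutive knots (where env < curve,
  # second differences in frequency are zero)
  interior <- which(env < y - 1e-9)
  if (length(interior) > 2) {
    runs <- split(interior, cumsum(c(1, diff(interior) != 1)))
    for (r in runs) {
      if (length(r) >= 3) {
        expect_lt(max(abs(diff(diff(env[r])))), 1e-9)
      }
    }
  }
})

test_that("envelope scales with the spectrum and adjustment is exact arithmetic", {
  set.seed(3)
  freqs <- (0:200) * 0.011
  y <- abs(rnorm(201, 1, 0.2)) + 0.1
  env <- lower_envelope(y, freqs)
  expect_equal(lower_envelope(5 * y, freqs), 5 * env, tolerance = 1e-12)
  # smoothed == envelope -> adjusted identically zero
  expect_equal(adjust_spectrum(env, env), rep(0, 201))
  expect_equal(adjust_spectrum(2 * env, env), rep(1, 201), tolerance = 1e-12)
  expect_error(adjust_spectrum(c(1, 2), c(1, 0)), "envelope")
})

test_that("primary peaks use the mean + std threshold over local maxima", {
  freqs <- (0:120) * 0.02
  flat <- rep(0, 121)
  expect_equal(nrow(detect_primary_peaks(flat, freqs)), 0)
  # one dominant bump over near-zero background
  y <- 0.01 * sin(freqs * 40)^2
  y[50:54] <- c(0.5, 1.2, 1.8, 1.2, 0.5)
  pk <- detect_primary_peaks(y, freqs)
  expect_equal(pk$index, 52L)
  # brute-force check: all local maxima above mean+sd (DC excluded)
  thr <- mean(y[-1]) + sd(y[-1])
  brute <- Filter(function(i) y[i] >= thr,
                  (2:120)[y[2:120] > y[1:119] & y[2:120] > y[3:121]])
  expect_equal(pk$index, as.integer(brute))
  # two equal, well-separated bumps are both returned
  y2 <- rep(0, 121)
  y2[c(30, 90)] <- 1
  y2[c(29, 31, 89, 91)] <- 0.4
  expect_equal(detect_primary_peaks(y2, freqs)$index, c(30L, 90L))
})

test_that("flat-topped maxima count once at the centre bin", {
  freqs <- (0:20) * 0.1
  y <- rep(0, 21)
  y[9:12] <- 1 # plateau of 4
  pk <- detect_primary_peaks(y, freqs)
  expect_equal(pk$index, 10L) # centre, tie toward lower frequency
})

test_that("baseline excludes a cardiac-width zone around each primary peak", {
  g <- make_frequency_grid(600, 0.155)
  freqs <- g$frequencies
  adj <- rep(0.1, length(freqs))
  pk <- tibble::tibble(index = which.min(abs(freqs - 1.2)),
                       frequency = freqs[which.min(abs(freqs - 1.2))],
                       height = 1)
  bs <- baseline_stats(adj, freqs, pk)
  f0 <- pk$frequency
  half <- peak_params()$exclusion_zone_hz / 2 # (100-60)/120 bpm, ~0.3335 Hz
  excluded <- which(!bs$baseline_bins)
  excluded <- excluded[excluded > 1] # drop DC
  expect_true(all(abs(freqs[excluded] - f0) <= half + 1e-9))
  kept <- which(bs$baseline_bins)
  expect_true(all(abs(freqs[kept] - f0) > half - 1e-9))
  # interval arithmetic: exclusion spans f0 +/- half
  expect_equal(range(freqs[excluded]),
               c(min(freqs[abs(freqs - f0) <= half]),
                 max(freqs[abs(freqs - f0) <= half])))
  # no primary peaks: baseline over everything but DC
  bs0 <- baseline_stats(adj, freqs, pk[0, ])
  expect_equal(sum(bs0$baseline_bins), length(freqs) - 1)
  # peaks tiling the whole axis: error
  many <- tibble::tibble(index = seq(2, length(freqs), by = 20),
                         frequency = freqs[seq(2, length(freqs), by = 20)],
                         height = 1)
  expect_error(baseline_stats(adj, freqs, many), "Exclusion")
})

test_that("final peaks respect both the baseline threshold and dB prominence", {
  freqs <- (0:150) * 0.02
  flat <- rep(0, 151)
  bs <- list(mean = 0, sd = 0)
  expect_equal(nrow(detect_final_peaks(flat, freqs, bs)), 0)
  # bump of ratio 2 (about 6 dB) passes
  y <- rep(0, 151)
  y[70:74] <- c(0.3, 0.7, 1, 0.7, 0.3)
  out <- detect_final_peaks(y, freqs, bs)
  expect_equal(out$index, 72L)
  expect_equal(out$prominence_db, 20 * log10(2), tolerance = 1e-9)
  # bump with prominence below 1.5 dB is suppressed
  y2 <- rep(0, 151)
  y2[70:74] <- c(0.05, 0.1, 10^(1.1 / 20) - 1, 0.1, 0.05)
  expect_equal(nrow(detect_final_peaks(y2, freqs, bs)), 0)
  # prominence equals the definition-based oracle on a rugged curve
  set.seed(21)
  yr <- abs(cumsum(rnorm(151, 0, 0.2)))
  db <- 20 * log10(1 + yr)
  for (i in csfpulse:::local_maxima(yr)) {
    expect_equal(csfpulse:::peak_prominences(db, i), naive_prominence(db, i),
                 tolerance = 1e-12)
  }
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(13)
  for (rep in 1:5) {
    sp <- random_spectrum()
    prev <- Inf
    found_prev <- NULL
    for (prom in c(0.5, 1.5, 3, 6)) {
      pars <- peak_params(min_prominence_db = prom)
      pk <- identify_peaks(sp, pars)$peaks
      if (!is.null(found_prev)) {
        expect_true(all(pk$frequency %in% found_prev$frequency))
      }
      found_prev <- pk
    }
  }
})

test_that("detected peak frequencies are invariant to spectrum rescaling", {
  ph <- make_phantom(small_phantom_spec(seed = 8))
  sp <- roi_spectrum(ph$image, ph$truth$masks$csf, provenance = "csf")
  an1 <- identify_peaks(sp)
  for (c0 in c(0.01, 7, 1e4)) {
    sp2 <- sp
    sp2$magnitude <- sp$magnitude * c0
    an2 <- identify_peaks(sp2)
    expect_equal(an2$peaks$frequency, an1$peaks$frequency)
    expect_equal(an2$stages$adjusted, an1$stages$adjusted, tolerance = 1e-9)
  }
})

test_that("adjusted-spectrum invariants hold across random spectra", {
  set.seed(2024)
  p <- peak_params()
  # stage-level invariants on rough white-noise magnitude curves
  for (rep in 1:50) {
    n <- sample(80:400, 1)
    freqs <- (0:(n - 1)) * 0.011
    spr <- csfpulse:::new_spectrum(freqs, rough_spectrum_values(n),
                                   n, 1 / (n * 0.011), "rough")
    sm <- pmax(smooth_spectrum(spr, p), 0)
    env <- lower_envelope(sm, freqs)
    adj <- adjust_spectrum(sm, env)
    expect_true(all(env <= sm + 1e-9))
    expect_true(all(env > 0))
    expect_true(all(adj >= 0))
  }
  # full-procedure invariants on realistic structured spectra
  for (rep in 1:25) {
    sp <- random_spectrum(n = sample(150:400, 1))
    an <- identify_peaks(sp)
    st <- an$stages
    expect_true(all(st$envelope <= st$smoothed + 1e-9))
    expect_true(all(st$envelope > 0))
    expect_true(all(st$adjusted >= 0))
    # final peaks are local maxima above the baseline threshold
    if (nrow(an$peaks)) {
      expect_true(all(an$peaks$index %in%
                        c(csfpulse:::local_maxima(st$adjusted))))
      expect_true(all(an$peaks$height >=
                        an$baseline$mean + an$baseline$sd - 1e-12))
      expect_true(all(an$peaks$prominence_db >= 1.5))
    }
  }
})

test_that("constant spectra yield a clean empty analysis", {
  sp <- voxel_spectrum(rep(5, 64), tr = 0.25)
  an <- identify_peaks(sp)
  expect_equal(nrow(an$peaks), 0)
  expect_true(all(an$stages$adjusted == 0))
})
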