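# 3 dB bands, grouping, cross-subject summaries.

# Minimal peak_analysis carrying a prescribed adjusted curve.
fake_analysis <- function(freqs, adjusted, peak_index) {
  structure(
    list(
      stages = tibble::tibble(frequency = freqs, raw = adjusted,
                              smoothed = adjusted,
                              envelope = rep(1e-9, length(freqs)),
                              adjusted = adjusted),
      peaks = tibble::tibble(index = as.integer(peak_index),
                             frequency = freqs[peak_index],
                             height = adjusted[peak_index],
                             prominence_db = 20 * log10(1 + adjusted[peak_index])),
      baseline = list(mean = 0, sd = 0),
      params = peak_params(),
      provenance = "synthetic", tr = 0.155, n_samples = 600
    ),
    class = "peak_analysis"
  )
}

test_that("triangular peak geometry: bandwidth (1 - sqrt2/2)*W, area W/4", {
  freqs <- (0:400) * 0.005
  f0 <- 1.0
  W <- 0.4
  adjusted <- pmax(0, 1 - abs(freqs - f0) / (W / 2))
  an <- fake_analysis(freqs, adjusted, which(freqs == f0))
  b <- band_from_peak(an, 1)
  expect_equal(b$bandwidth, W * (1 - sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(b$center_frequency, f0)
  expect_equal(b$magnitude, 1)
  expect_equal(b$area, W / 4, tolerance = 1e-9) # (1 - thr^2) * W / 2 with thr^2 = 1/2
  expect_false(b$truncated)
})

test_that("gaussian peak: 3 dB width approximates 2*sigma*sqrt(ln 2)", {
  delta <- 0.011
  freqs <- (0:300) * delta
  sigma <- 0.05
  f0 <- 1.5
  adjusted <- 2 * exp(-(freqs - f0)^2 / (2 * sigma^2))
  i0 <- which.min(abs(freqs - f0))
  an <- fake_analysis(freqs, adjusted, i0)
  b <- band_from_peak(an, 1)
  expect_equal(b$bandwidth, 2 * sigma * sqrt(log(2)), tolerance = delta)
  expect_true(abs(b$f_lo - (f0 - sigma * sqrt(log(2)))) < delta)
})

test_that("edge and valley truncation are flagged", {
  freqs <- (0:100) * 0.02
  # monotone rise to the upper grid edge
  adjusted <- seq(0, 2, length.out = 101)
  an <- fake_analysis(freqs, adjusted, 101L)
  # index 101 is the last bin: not a local max, but band_from_peak accepts it
  b <- band_from_peak(an, tibble::tibble(index = 101L, frequency = freqs[101],
                                         height = 2))
  expect_true(b$truncated)
  expect_equal(b$f_hi, max(freqs))
  # two peaks with a valley that stays above threshold: the search stops
  # at the valley before the taller neighbour
  y <- rep(0, 101)
  y[30:50] <- c(seq(0, 2, length.out = 11), seq(1.96, 1.6, length.out = 10))
  y[51:70] <- seq(1.7, 4, length.out = 20) # taller neighbour
  an2 <- fake_analysis(freqs, y, 40L)
  b2 <- band_from_peak(an2, 1)
  expect_true(b2$truncated)
  # the right edge sits at the valley between the peaks, before the taller one
  expect_true(b2$f_hi <= freqs[51])
  expect_gte(b2$f_hi, freqs[40])
})

test_that("band edges stop at the first threshold crossing", {
  # curve dips below threshold then rises again within the band's reach
  freqs <- (0:200) * 0.01
  y <- 0.2 + 0.8 * exp(-(freqs - 1)^2 / (2 * 0.03^2)) +
    0.5 * exp(-(freqs - 1.3)^2 / (2 * 0.03^2))
  i0 <- which.min(abs(freqs - 1))
  an <- fake_analysis(freqs, y, i0)
  b <- band_from_peak(an, 1)
  thr <- y[i0] * sqrt(2) / 2
  # brute-force first crossing on each side
  right <- which(freqs > 1 & y < thr)[1]
  left <- max(which(freqs < 1 & y < thr))
  expect_true(b$f_hi <= freqs[right] && b$f_hi >= freqs[right - 1])
  expect_true(b$f_lo >= freqs[left] && b$f_lo <= freqs[left + 1])
  # interior of the band stays above threshold for this unimodal stretch
  inside <- freqs > b$f_lo & freqs < b$f_hi
  expect_true(all(y[inside] >= thr - 1e-9))
})

test_that("area is bounded by peak-height and triangular envelopes", {
  set.seed(5)
  delta <- 0.011
  freqs <- (0:300) * delta
  for (rep in 1:20) {
    sigma <- runif(1, 0.02, 0.1)
    h <- runif(1, 0.5, 3)
    f0 <- runif(1, 0.8, 2.5)
    y <- h * exp(-(freqs - f0)^2 / (2 * sigma^2))
    i0 <- which.min(abs(freqs - f0))
    an <- fake_analysis(freqs, y, i0)
    b <- band_from_peak(an, 1)
    expect_lte(b$area, b$magnitude * b$bandwidth + 1e-9)
    expect_gte(b$area, sqrt(2) / 2 * b$magnitude * b$bandwidth / 2 - 1e-9)
  }
})

test_that("bands group by single-linkage clustering of centre frequency", {
  centers <- c(1.151, 1.312, 1.151, 1.129, 1.226)
  g <- group_bands(tibble::tibble(center_frequency = centers), 0.2)
  expect_equal(length(unique(g$band_label)), 1L)
  g2 <- group_bands(tibble::tibble(center_frequency = c(0.3, 1.2)), 0.2)
  expect_equal(as.character(g2$band_label), c("Band 1", "Band 2"))
  g0 <- group_bands(tibble::tibble(center_frequency = numeric(0)))
  expect_equal(nrow(g0), 0L)
  expect_true("band_label" %in% names(g0))
})

test_that("band summaries reproduce the published per-volunteer statistics", {
  bands <- example_band_table()
  csf <- dplyr::filter(bands, region == "csf")
  s <- summarize_bands(csf)
  b1 <- dplyr::filter(s, band_label == "Band 1")
  b4 <- dplyr::filter(s, band_label == "Band 4")
  expect_equal(round(b1$magnitude_mean, 3), 0.594)
  expect_equal(round(b1$magnitude_sd, 3), 0.378)
  expect_equal(round(b4$magnitude_mean, 3), 1.747)
  expect_equal(round(b4$magnitude_sd, 3), 0.475)
  expect_equal(round(b1$area_mean, 3), 0.027)
  expect_equal(round(b1$area_sd, 3), 0.017)
  expect_equal(round(b4$area_mean, 3), 0.119)
  expect_equal(round(b4$area_sd, 3), 0.037)
  expect_equal(round(b1$bandwidth_mean, 3), 0.053)
  expect_equal(round(b4$bandwidth_mean, 3), 0.078)
  # sample (n-1) convention pinned by the published two-subject band
  b2 <- dplyr::filter(s, band_label == "Band 2")
  expect_equal(round(b2$center_frequency_sd, 3), 0.023)
  expect_equal(b2$center_frequency_sd, sd(c(0.516, 0.484)))
})

test_that("single-subject groups report mean without a standard deviation", {
  one <- tibble::tibble(center_frequency = 1.2, magnitude = 2, area = 0.1,
                        bandwidth = 0.07,
                        band_label = factor("Band 1"))
  s <- summarize_bands(one)
  expect_equal(s$magnitude_mean, 2)
  expect_true(is.na(s$magnitude_sd))
  expect_equal(s$n_subjects, 1L)
})

test_that("band tables export with standard column names", {
  bands <- dplyr::mutate(example_band_table(), truncated = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_bands(bands, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("region", "subject", "band_label", "frequency_hz",
                    "magnitude_au", "area_hz", "bandwidth_hz") %in% names(tab)))
  expect_equal(nrow(tab), nrow(bands))
})
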