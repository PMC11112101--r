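# Independent oracles and small fixture builders used across the suite.

# Brute-force O(T^2) one-sided amplitude spectrum: the DFT written as an
# explicit summation, scaled 2/T interior, 1/T at DC and (even T) Nyquist.
naive_dft_mag <- function(x, tr) {
  n <- length(x)
  x <- x - mean(x)
  nb <- n %/% 2 + 1
  mag <- numeric(nb)
  t_idx <- 0:(n - 1)
  for (k in 0:(nb - 1)) {
    re <- sum(x * cos(-2 * pi * k * t_idx / n))
    im <- sum(x * sin(-2 * pi * k * t_idx / n))
    mag[k + 1] <- sqrt(re^2 + im^2)
  }
  scale <- rep(2 / n, nb)
  scale[1] <- 1 / n
  if (n %% 2 == 0) scale[nb] <- 1 / n
  mag * scale
}

# Sliding local least-squares quadratic fit: the definition of a
# Savitzky-Golay order-2 filter. Interior points use a centred window; the
# first/last half-windows evaluate the polynomial fitted over the first/last
# full window.
naive_sgolay <- function(y, w) {
  n <- length(y)
  h <- (w - 1) %/% 2
  fit_window <- function(idx, at) {
    xx <- idx - mean(idx)
    co <- stats::coef(stats::lm(y[idx] ~ xx + I(xx^2)))
    at0 <- at - mean(idx)
    co[1] + co[2] * at0 + co[3] * at0^2
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= h) {
      out[i] <- fit_window(1:w, i)
    } else if (i > n - h) {
      out[i] <- fit_window((n - w + 1):n, i)
    } else {
      out[i] <- fit_window((i - h):(i + h), i)
    }
  }
  unname(out)
}

# Definition-based topographic prominence on a curve.
naive_prominence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  left <- if (i > 1) y[1:(i - 1)] else numeric(0)
  right <- if (i < n) y[(i + 1):n] else numeric(0)
  base_side <- function(side, rev) {
    if (!length(side)) return(min(y[i], h))
    if (rev) side <- rev(side)
    higher <- which(side > h)
    seg <- if (length(higher)) side[seq_len(higher[1] - 1)] else side
    if (!length(seg)) h else min(seg)
  }
  lb <- base_side(left, rev = TRUE)
  rb <- base_side(right, rev = FALSE)
  h - max(lb, rb)
}

# Random realistic spectrum: decreasing 1/sqrt(f) floor, a few Gaussian
# bumps, mild multiplicative noise. Mirrors the structure of EPI ROI
# spectra.
random_spectrum <- function(n = 301, tr = 0.155, n_samples = 600,
                            max_bumps = 3) {
  freqs <- (0:(n - 1)) / (n_samples * tr)
  a <- stats::runif(1, 0.2, 1)
  c0 <- stats::runif(1, 0.05, 0.3)
  mag <- a * pmax(freqs, freqs[2])^(-0.5) + c0
  for (b in seq_len(sample(max_bumps, 1))) {
    f0 <- stats::runif(1, 0.15, max(freqs) * 0.95)
    h <- stats::runif(1, 0.2, 3) * mag[which.min(abs(freqs - f0))]
    w <- stats::runif(1, 0.02, 0.06)
    mag <- mag + h * exp(-(freqs - f0)^2 / (2 * w^2))
  }
  mag <- mag * (1 + stats::rnorm(n, 0, 0.05))
  mag <- pmax(mag, 1e-6)
  mag[1] <- 0
  csfpulse:::new_spectrum(freqs, mag, n_samples, tr, "random")
}

# Rough positive spectrum (white-noise magnitudes) for stage-level
# invariant checks.
rough_spectrum_values <- function(n = 301) {
  abs(stats::rnorm(n, mean = 1, sd = 0.3)) + 0.05
}

# Tiny phantom spec used in fast tests.
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(12L, 12L, 6L, 200L), seed = seed, ...)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
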