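# Shared numeric helpers: extrema with plateau handling, topographic
# prominence, trapezoidal integration.

# Indices of local maxima. A flat-topped run counts as one maximum at its
# centre bin, ties broken toward the lower index. Endpoints never qualify.
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1L)
  hit <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  i <- i[hit]
  starts[i] + (ends[i] - starts[i]) %/% 2L
}

# Strict local minima (plateau bins excluded); used for envelope knots.
strict_local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] < x[i - 1L] & x[i] < x[i + 1L]]
}

# Topographic prominence of peaks on curve y: height above the higher of the
# two key saddles, where each side extends to the nearest strictly higher
# sample or to the curve edge.
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      if (y[j] < lmin) lmin <- y[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      if (y[j] < rmin) rmin <- y[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Trapezoidal integral of y(x).
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
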