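# Spatial localization of frequency bands: per-voxel band power maps,
# fractional-peak binarization, Gaussian mask smoothing, NIfTI export.

band_bin_range <- function(frequencies, band) {
  which(frequencies >= band$f_lo[[1]] & frequencies <= band$f_hi[[1]])
}

# Mean over band bins of a bins x V magnitude matrix -> 3D array.
band_power_from_mags <- function(mags, frequencies, band, spatial_dim,
                                 use_power = FALSE) {
  rows <- band_bin_range(frequencies, band)
  if (!length(rows)) {
    abort(sprintf("band [%.3f, %.3f] Hz contains no frequency bins.",
                  band$f_lo[[1]], band$f_hi[[1]]))
  }
  m <- mags[rows, , drop = FALSE]
  if (use_power) m <- m^2
  vals <- colMeans(m)
  array(vals, dim = spatial_dim)
}

#' Per-voxel band power map
#'
#' For each voxel, the mean of its magnitude-spectrum values over the
#' frequency bins falling inside the band `[f_lo, f_hi]`. With
#' `use_power = TRUE` magnitudes are squared first.
#'
#' @param image An [as_image4d()] object.
#' @param band One-row band tibble (from [band_from_peak()] or a row of
#'   [bands_from_peaks()]).
#' @param use_power Square the magnitudes before averaging.
#' @param chunk Voxels per FFT block.
#' @return A `band_power_map` object: list with the 3D `values` array, the
#'   `band` row, and the source affine/voxel size.
#' @export
band_power_map <- function(image, band, use_power = FALSE, chunk = 4096L) {
  if (!inherits(image, "image4d")) abort("`image` must be an image4d.")
  sp <- dim(image$data)[1:3]
  n <- dim(image$data)[4]
  grid <- make_frequency_grid(n, image$tr)
  rows <- band_bin_range(grid$frequencies, band)
  if (!length(rows)) {
    abort(sprintf("band [%.3f, %.3f] Hz contains no frequency bins.",
                  band$f_lo[[1]], band$f_hi[[1]]))
  }
  flat <- image$data
  dim(flat) <- c(prod(sp), n)
  vals <- numeric(prod(sp))
  idx <- seq_len(prod(sp))
  for (block in split(idx, ceiling(idx / chunk))) {
    mags <- spectral_matrix(t(flat[block, , drop = FALSE]), image$tr)
    m <- mags[rows, , drop = FALSE]
    if (use_power) m <- m^2
    vals[block] <- colMeans(m)
  }
  structure(
    list(values = array(vals, dim = sp), band = band,
         affine = image$affine, voxel_size = image$voxel_size),
    class = "band_power_map"
  )
}

#' Binarize a band power map at a fraction of its peak
#'
#' @param map A `band_power_map`.
#' @param fraction Threshold as a fraction of the map maximum (default
#'   0.75).
#' @param quantile_fraction If non-`NULL`, threshold at this quantile of
#'   the positive map values instead (robust alternative).
#' @return A `band_mask` object (logical 3D array plus provenance).
#' @export
binarize_map <- function(map, fraction = 0.75, quantile_fraction = NULL) {
  if (!inherits(map, "band_power_map")) abort("`map` must be a band_power_map.")
  mx <- max(map$values)
  if (mx <= 0) abort("band power map is identically zero; nothing to binarize.")
  thr <- if (!is.null(quantile_fraction)) {
    stats::quantile(map$values[map$values > 0], quantile_fraction, names = FALSE)
  } else {
    stopifnot_scalar_number(fraction, "fraction")
    fraction * mx
  }
  structure(
    list(mask = map$values >= thr, band = map$band, threshold_value = thr,
         sigma = NULL, affine = map$affine, voxel_size = map$voxel_size),
    class = "band_mask"
  )
}

# 1D Gaussian kernel, truncated at 3 sigma, unit sum.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable zero-padded Gaussian blur along the given axes of a 3D array.
gaussian_blur <- function(arr, sigma, axes = 1:3) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  for (ax in axes) {
    d <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(arr, perm)
    n <- dim(x)[1]
    m <- matrix(x, nrow = n)
    # dense convolution matrix with zero padding outside the grid
    conv <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      conv[cbind(i[ok], j[ok])] <- conv[cbind(i[ok], j[ok])] + k[off + r + 1L]
    }
    m <- conv %*% m
    x <- array(m, dim = dim(x))
    arr <- aperm(x, order(perm))
  }
  arr
}

#' Gaussian-smooth a band mask
#'
#' Blurs the binary mask with an isotropic Gaussian (sigma in voxel units)
#' and re-binarizes at 0.5, the symmetric cut: isolated speckles vanish,
#' large solid regions keep their interior, and boundaries are rounded.
#' `sigma = 0` is the identity. `dims = 2` smooths slice-wise (in-plane
#' only).
#'
#' @param mask A `band_mask`.
#' @param sigma Gaussian standard deviation in voxels (>= 0).
#' @param dims 3 for volumetric smoothing (default) or 2 for slice-wise.
#' @return The smoothed `band_mask` (with `sigma` recorded).
#' @export
smooth_mask <- function(mask, sigma = 1.6, dims = 3) {
  if (!inherits(mask, "band_mask")) abort("`mask` must be a band_mask.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  out <- mask
  if (sigma > 0) {
    axes <- if (dims == 2) 1:2 else 1:3
    sm <- gaussian_blur(mask$mask * 1, sigma, axes = axes)
    out$mask <- sm >= 0.5
  }
  out$sigma <- sigma
  out
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical arrays (or `band_mask` objects) of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "band_mask")) a <- a$mask
  if (inherits(b, "band_mask")) b <- b$mask
  if (!all(dim(a) == dim(b))) abort("mask shapes differ.")
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Export band masks as NIfTI files
#'
#' One file per mask, named by the band centre frequency
#' (`mask_band_<freq>Hz.nii.gz`), written on the EPI grid of `reference`.
#'
#' @param masks A `band_mask` or list of them.
#' @param reference The `image4d` the masks were derived from (affine must
#'   match).
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
export_masks <- function(masks, reference, dir) {
  if (inherits(masks, "band_mask")) masks <- list(masks)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in masks) {
    if (!isTRUE(all.equal(m$affine, reference$affine))) {
      abort("mask affine does not match the reference image.")
    }
    f0 <- m$band$center_frequency[[1]]
    path <- file.path(dir, sprintf("mask_band_%.3fHz.nii.gz", f0))
    write_nifti(m$mask * 1L, path, reference = reference)
    paths <- c(paths, path)
  }
  invisible(paths)
}
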