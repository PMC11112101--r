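# 4D EPI time-series container and integer label maps. Images are plain R
# arrays wrapped with acquisition metadata; everything derived from them
# (spectra, peaks, bands) is tabular.

#' Create a 4D EPI image object
#'
#' Wraps a real-valued `X x Y x Z x T` array with the acquisition metadata the
#' spectral pipeline needs: the repetition time (TR, the temporal sampling
#' interval in seconds), voxel size and a 4x4 spatial affine.
#'
#' @param data Numeric 4D array (`X x Y x Z x T`) of magnitude values (a.u.).
#'   All values must be finite and non-negative.
#' @param tr Repetition time in seconds (> 0).
#' @param voxel_size Numeric length-3 voxel dimensions in mm.
#' @param affine 4x4 numeric voxel-to-world transform. Defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `image4d`.
#' @examples
#' img <- as_image4d(array(100, dim = c(2, 2, 2, 8)), tr = 0.155)
#' dim(img$data)
#' @export
as_image4d <- function(data, tr, voxel_size = c(2, 2, 2), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D array (X x Y x Z x T).")
  }
  if (dim(data)[4] < 2L) abort("At least 2 volumes (T >= 2) are required.")
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  if (anyNA(data) || !all(is.finite(data))) abort("`data` contains non-finite values.")
  if (min(data) < 0) abort("EPI magnitude data must be non-negative.")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 positive numbers (mm).")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    abort("`affine` must be a 4x4 matrix.")
  }
  structure(
    list(data = data, tr = tr, voxel_size = as.numeric(voxel_size), affine = affine),
    class = "image4d"
  )
}

#' @export
print.image4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image4d> %d x %d x %d voxels, %d volumes, TR = %g s (%.3f min)\n",
    d[1], d[2], d[3], d[4], x$tr, d[4] * x$tr / 60
  ))
  invisible(x)
}

#' Create a label map
#'
#' An integer segmentation aligned to an [as_image4d()] grid. Label 0 is
#' background; `scheme` names the remaining labels (typically `csf`, `cgm`
#' for cortical grey matter, `cwm` for cerebral white matter).
#'
#' @param labels Integer 3D array; non-negative, 0 = background.
#' @param scheme Named integer vector mapping region name to label value,
#'   e.g. `c(csf = 1, cgm = 2, cwm = 3)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, scheme = c(csf = 1L, cgm = 2L, cwm = 3L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D array.")
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    abort("labels must be non-negative integers.")
  }
  if (is.null(names(scheme)) || any(!nzchar(names(scheme)))) {
    abort("`scheme` must be a named vector of label values.")
  }
  structure(list(labels = labels, scheme = scheme), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d\n", d[1], d[2], d[3]))
  for (nm in names(x$scheme)) {
    cat(sprintf("  %s (label %d): %d voxels\n", nm, x$scheme[[nm]],
                sum(x$labels == x$scheme[[nm]])))
  }
  invisible(x)
}

#' Read a 4D NIfTI file as an image4d
#'
#' The TR passed explicitly is authoritative; when `tr = NULL` it falls back
#' to the time-axis `pixdim` stored in the NIfTI header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file with 4 dimensions.
#' @param tr Repetition time in seconds, or `NULL` to use the header value.
#' @return An [as_image4d()] object.
#' @export
read_image4d <- function(path, tr = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L) abort(sprintf("'%s' is not a 4D image.", path))
  pix <- RNifti::pixdim(nii)
  if (is.null(tr)) {
    tr <- if (length(pix) >= 4) pix[4] else NA_real_
    if (!is.finite(tr) || tr <= 0) {
      abort("No usable TR in the NIfTI header; pass `tr` explicitly.")
    }
  }
  as_image4d(arr, tr = tr, voxel_size = pix[1:3], affine = structure(RNifti::xform(nii), dim = c(4L, 4L)))
}

#' Write an image4d (or 3D array) to NIfTI
#'
#' @param x An `image4d`, `label_map`, or numeric array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param reference Optional `image4d` supplying voxel size/affine when `x`
#'   is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, reference = NULL) {
  if (inherits(x, "image4d")) {
    arr <- x$data
    vox <- x$voxel_size
    tr <- x$tr
  } else if (inherits(x, "label_map")) {
    arr <- x$labels
    vox <- if (!is.null(reference)) reference$voxel_size else c(1, 1, 1)
    tr <- NULL
  } else {
    arr <- x
    vox <- if (!is.null(reference)) reference$voxel_size else c(1, 1, 1)
    tr <- NULL
  }
  pix <- if (is.null(tr)) vox else c(vox, tr)
  nii <- RNifti::asNifti(arr, pixdim = pix)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read an integer label map from NIfTI
#'
#' @inheritParams read_image4d
#' @param scheme Named vector mapping region names to label values.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, scheme = c(csf = 1L, cgm = 2L, cwm = 3L)) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  label_map(round(arr), scheme = scheme)
}

#' Merge axial slabs into one 4D volume
#'
#' Whole-brain ultrafast EPI is often acquired as several thin axial slabs
#' (e.g. 19 slabs of 3 slices); this stacks them along the slice axis in the
#' order given. All slabs must share the in-plane shape, the number of
#' volumes and the TR. The output takes the first slab's affine.
#'
#' @param slabs List of `image4d` objects ordered inferior to superior.
#' @return A single `image4d` with the slices concatenated.
#' @examples
#' sl <- replicate(3, as_image4d(array(1, c(4, 4, 2, 6)), tr = 0.155),
#'                 simplify = FALSE)
#' dim(merge_slabs(sl)$data)
#' @export
merge_slabs <- function(slabs) {
  if (!length(slabs)) abort("`slabs` is empty.")
  if (!all(vapply(slabs, inherits, logical(1), "image4d"))) {
    abort("All slabs must be image4d objects.")
  }
  if (length(slabs) == 1L) return(slabs[[1]])
  d1 <- dim(slabs[[1]]$data)
  for (i in seq_along(slabs)[-1]) {
    d <- dim(slabs[[i]]$data)
    if (!all(d[c(1, 2, 4)] == d1[c(1, 2, 4)])) {
      abort(sprintf("Slab %d shape (%s) does not match slab 1 (%s).",
                    i, paste(d, collapse = "x"), paste(d1, collapse = "x")))
    }
    if (slabs[[i]]$tr != slabs[[1]]$tr) {
      abort(sprintf("Slab %d TR (%g s) differs from slab 1 (%g s).",
                    i, slabs[[i]]$tr, slabs[[1]]$tr))
    }
  }
  nz <- vapply(slabs, function(s) dim(s$data)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(nz), d1[4]))
  z0 <- 0L
  for (s in slabs) {
    k <- dim(s$data)[3]
    out[, , z0 + seq_len(k), ] <- s$data
    z0 <- z0 + k
  }
  inform(sprintf("Merged %d slabs (%s slices) into a %d-slice volume.",
                 length(slabs), paste(nz, collapse = "+"), sum(nz)))
  as_image4d(out, tr = slabs[[1]]$tr, voxel_size = slabs[[1]]$voxel_size,
             affine = slabs[[1]]$affine)
}
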