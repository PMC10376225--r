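#' MRI volume container
#'
#' A light container for a single-channel 3D image: the voxel array, per-axis
#' spacing in millimetres, and the 4x4 voxel-to-world affine. Intensities are
#' held as doubles regardless of the on-disk type because the downstream
#' filters need real arithmetic.
#'
#' @param data Numeric 3D array of intensities.
#' @param spacing Numeric length-3 vector of voxel sizes (mm), all > 0.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return An object of class `mri_volume` with elements `data`, `spacing`,
#'   `affine`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got dimensions [",
         paste(dim(data), collapse = " x "), "]")
  if (any(dim(data) < 1L)) stop("volume dimensions must be positive")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  storage.mode(data) <- "double"
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("<mri_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' MRI slice container
#'
#' @param data Numeric matrix of intensities.
#' @param spacing Length-2 (row, col) pixel size in mm.
#' @param index 1-based position of the slice within its parent volume.
#' @return An object of class `mri_slice`.
#' @export
mri_slice <- function(data, spacing = c(1, 1), index = NA_integer_) {
  if (!is.matrix(data)) stop("slice data must be a matrix")
  if (any(dim(data) < 1L)) stop("slice dimensions must be positive")
  if (!all(is.finite(data))) stop("slice intensities must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 index = as.integer(index)),
            class = "mri_slice")
}

#' @export
print.mri_slice <- function(x, ...) {
  cat("<mri_slice> ", paste(dim(x$data), collapse = " x "),
      if (!is.na(x$index)) paste0(" (index ", x$index, ")"), "\n", sep = "")
  invisible(x)
}

#' Read a single-channel NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [mri_volume]. Only 3D single-channel
#' images are accepted; anything else raises an unsupported-format error
#' naming the offending shape.
#'
#' @param path Path to a NIfTI file.
#' @return An [mri_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("unsupported image shape [", paste(d, collapse = " x "),
         "]: expected a 3D single-channel volume")
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  aff <- unclass(RNifti::xform(img))
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  data <- array(as.double(img), dim = d)
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  mri_volume(data, spacing = spacing, affine = aff)
}

#' Write a volume to NIfTI
#'
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param v An [mri_volume].
#' @export
save_volume <- function(path, v) {
  stopifnot(inherits(v, "mri_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to NIfTI
#'
#' The mask is stored as unsigned 8-bit 0/1 voxels with the template's
#' spacing and affine.
#'
#' @param path Output path.
#' @param m Logical (or 0/1) array matching the template's dimensions.
#' @param template [mri_volume] providing geometry.
#' @export
save_mask <- function(path, m, template) {
  stopifnot(inherits(template, "mri_volume"))
  md <- if (is.list(m) && !is.null(m$data)) m$data else m
  if (!identical(dim(md), dim(template$data)))
    stop("mask shape [", paste(dim(md), collapse = " x "),
         "] does not match template [",
         paste(dim(template$data), collapse = " x "), "]")
  arr <- array(as.integer(md != 0), dim = dim(md))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- template$spacing
  RNifti::sform(img) <- structure(template$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load a mask written by [save_mask]
#'
#' @param path NIfTI path.
#' @return Logical 3D array.
#' @export
load_mask <- function(path) {
  v <- load_volume(path)
  v$data != 0
}

plane_axis <- function(plane) {
  switch(match.arg(plane, c("axial", "coronal", "sagittal")),
         axial = 3L, coronal = 2L, sagittal = 1L)
}

#' Split a volume into an ordered stack of 2D slices
#'
#' The axial plane is spanned by the first two array axes (slice index runs
#' along the third); coronal and sagittal planes run along the second and
#' first axes respectively. Slice spacing is taken from the two in-plane axes.
#'
#' @param v An [mri_volume].
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return List of [mri_slice] objects, order preserved.
#' @export
volume_to_slices <- function(v, plane = "axial") {
  stopifnot(inherits(v, "mri_volume"))
  ax <- plane_axis(plane)
  inplane <- setdiff(1:3, ax)
  n <- dim(v$data)[ax]
  lapply(seq_len(n), function(k) {
    dat <- switch(ax,
                  `1` = v$data[k, , , drop = TRUE],
                  `2` = v$data[, k, , drop = TRUE],
                  `3` = v$data[, , k, drop = TRUE])
    if (!is.matrix(dat)) dat <- matrix(dat, nrow = dim(v$data)[inplane[1L]])
    mri_slice(dat, spacing = v$spacing[inplane], index = k)
  })
}

#' Restack 2D slices into a volume
#'
#' Inverse of [volume_to_slices]: all slices must share a shape and their
#' count must match the template's axis length; the result carries the
#' template's spacing and affine.
#'
#' @param slices List of [mri_slice] objects or matrices.
#' @param template [mri_volume] providing geometry.
#' @param plane Plane the slices were extracted along.
#' @return An [mri_volume].
#' @export
slices_to_volume <- function(slices, template, plane = "axial") {
  stopifnot(inherits(template, "mri_volume"))
  ax <- plane_axis(plane)
  n <- dim(template$data)[ax]
  if (length(slices) != n)
    stop("slice count ", length(slices), " does not match template axis length ", n)
  mats <- lapply(slices, slice_data)
  shp <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1L))))
    stop("slices do not share a common shape")
  expected <- dim(template$data)[setdiff(1:3, ax)]
  if (!identical(as.integer(shp), as.integer(expected)))
    stop("slice shape [", paste(shp, collapse = " x "),
         "] does not match template in-plane shape [",
         paste(expected, collapse = " x "), "]")
  out <- array(0, dim = dim(template$data))
  for (k in seq_len(n)) {
    if (ax == 1L) out[k, , ] <- mats[[k]]
    else if (ax == 2L) out[, k, ] <- mats[[k]]
    else out[, , k] <- mats[[k]]
  }
  mri_volume(out, spacing = template$spacing, affine = template$affine)
}

#' Export a slice as a PNG for inspection
#'
#' Intensities are min-max normalized to 8 bits; this export is lossy and is
#' never read back into the pipeline.
#'
#' @param s [mri_slice] or matrix.
#' @param path Output PNG path.
#' @export
export_slice_png <- function(s, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  m <- slice_data(s)
  rng <- range(m)
  norm <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
  png::writePNG(t(norm), target = path)
  invisible(path)
}
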