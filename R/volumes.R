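#' Construct a gray-matter probability volume
#'
#' A `gm_volume` is one spatially normalized gray-matter (GM) probability
#' map together with its identity within a longitudinal study: the subject
#' it belongs to, the visit (imaging session) and the scan within that
#' visit. Every voxel holds the probability/proportion of that voxel being
#' gray matter, so values must lie in \[0, 1\]. Values straying outside by
#' at most `tol` (float noise from segmentation) are clipped; larger
#' excursions are an error.
#'
#' @param data 3D numeric array of GM probabilities.
#' @param subject_id Character scalar subject identifier.
#' @param visit_id 1-based visit (session) ordinal.
#' @param scan_id 1-based scan ordinal within the visit.
#' @param voxel_size_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @param tol Clipping tolerance for values outside \[0, 1\] (default 1e-6).
#' @return An object of class `gm_volume` with fields `data`, `subject_id`,
#'   `visit_id`, `scan_id`, `voxel_size_mm`.
#' @export
gm_volume <- function(data, subject_id, visit_id, scan_id,
                      voxel_size_mm = c(1, 1, 1), tol = 1e-6) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("GM map must be a 3D array, got ", length(dim(data)), " dimensions",
         call. = FALSE)
  }
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive lengths", call. = FALSE)
  }
  storage.mode(data) <- "double"
  lo <- min(data)
  hi <- max(data)
  if (lo < -tol || hi > 1 + tol) {
    stop(sprintf(
      "invalid GM map: voxel values in [%.6g, %.6g] exceed [0, 1] beyond tolerance %g",
      lo, hi, tol), call. = FALSE)
  }
  structure(
    list(
      data = clip01(data),
      subject_id = as.character(subject_id),
      visit_id = as.integer(visit_id),
      scan_id = as.integer(scan_id),
      voxel_size_mm = as.numeric(voxel_size_mm)
    ),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume> %s  grid %s  voxel %s mm  range [%.3f, %.3f]\n",
              format_scan_id(x$subject_id, x$visit_id, x$scan_id),
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.gm_volume <- function(x) dim(x$data)

#' Read a normalized GM probability volume from a NIfTI-1 file
#'
#' Reads a 3D NIfTI-1 image, validates that it is a GM probability map
#' (all voxels in \[0, 1\] up to a small clipping tolerance) and attaches
#' the subject/visit/scan identity. Voxel sizes are taken from the NIfTI
#' header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @inheritParams gm_volume
#' @return A validated [gm_volume()].
#' @export
read_gm_volume <- function(path, subject_id, visit_id, scan_id, tol = 1e-6) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), "D: ", path, call. = FALSE)
  }
  vox <- RNifti::pixdim(img)[seq_len(3)]
  gm_volume(array(as.numeric(img), dim = d), subject_id, visit_id, scan_id,
            voxel_size_mm = vox, tol = tol)
}

#' Write a GM probability volume to a NIfTI-1 file
#'
#' Data are stored as 64-bit floats so that [read_gm_volume()] inverts the
#' write bit-for-bit on the data grid.
#'
#' @param vol A [gm_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gm_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Discrete Gaussian kernel with sd `sigma` (voxels), truncated at 4 sigma,
# normalized to unit sum. sigma == 0 gives the identity kernel.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along the first axis of a 3D array with kernel `k`, renormalizing
# the kernel over its in-domain support at the boundaries so that constants
# are preserved exactly and values stay within the input's range.
convolve_axis1 <- function(arr, k) {
  n <- dim(arr)[1]
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-h, h)) {
    idx <- seq_len(n)
    keep <- idx + off >= 1L & idx + off <= n
    K[cbind(idx[keep], idx[keep] + off)] <- k[off + h + 1L]
  }
  K <- K / rowSums(K)
  array(K %*% matrix(arr, n, prod(dim(arr)[-1])), dim = dim(arr))
}

# Separable 3D Gaussian smoothing; sigma_vox is per-axis sd in voxels.
smooth_array_gaussian <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    if (length(k) == 1L) next
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    inv <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
    arr <- aperm(convolve_axis1(aperm(arr, perm), k), inv)
  }
  arr
}

#' Smooth a GM volume with an isotropic Gaussian filter
#'
#' Applies the standard neuroimaging preprocessing step of isotropic
#' Gaussian smoothing, parameterized by the kernel's full-width at
#' half-maximum in mm. The per-axis standard deviation in voxels is
#' `fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))`; the kernel is
#' truncated at 4 sigma and renormalized over its in-domain support at the
#' grid boundary, so constant volumes are unchanged and smoothing never
#' pushes values outside the input's range. Output is clipped to \[0, 1\].
#'
#' @param vol A [gm_volume()].
#' @param fwhm_mm Kernel full-width at half-maximum in mm; 0 is a no-op.
#' @return A new [gm_volume()] with the same identity metadata.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("fwhm_mm must be a nonnegative length in mm", call. = FALSE)
  }
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (vol$voxel_size_mm * (2 * sqrt(2 * log(2))))
  out <- vol
  out$data <- clip01(smooth_array_gaussian(vol$data, sigma_vox))
  out
}
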