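#' Voxel volumes
#'
#' A `voxel_volume` is a 3D scalar field on a regular grid: a numeric (or
#' integer, for label maps) array together with its voxel spacing in mm and
#' the world-space position of voxel (1,1,1). World coordinates follow the
#' convention `world = (index - 1) * spacing + origin`; rotations used
#' elsewhere in the package are taken about the volume centre.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing in mm, length-3 (or a scalar, recycled).
#' @param origin World coordinate of the first voxel, mm.
#' @param units Free-text unit tag carried along for bookkeeping
#'   (e.g. "Bq/ml", "1/cm", "Gy", "label").
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(data, spacing = c(4.8, 4.8, 4.8), origin = c(0, 0, 0),
                         units = "") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = units),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  cat(sprintf("  range [%.4g, %.4g], total volume %.1f ml\n",
              min(x$data), max(x$data), volume_ml(x)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Voxel volume in ml
#'
#' @param vol A `voxel_volume`.
#' @return For `voxel_size_ml`, the volume of one voxel in ml; for
#'   `volume_ml`, the total field-of-view volume in ml.
#' @export
voxel_size_ml <- function(vol) prod(vol$spacing) / 1000

#' @rdname voxel_size_ml
#' @export
volume_ml <- function(vol) voxel_size_ml(vol) * length(vol$data)

#' Total activity in a concentration volume
#'
#' Integrates a Bq/ml concentration field over the grid.
#'
#' @param vol A `voxel_volume` holding activity concentration in Bq/ml.
#' @return Total activity in MBq.
#' @export
total_activity_mbq <- function(vol) {
  sum(vol$data) * voxel_size_ml(vol) / 1e6
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

with_data <- function(vol, data, units = vol$units) {
  voxel_volume(data, spacing = vol$spacing, origin = vol$origin, units = units)
}

## 1D Gaussian convolution matrix. `normalize = "col"` makes every column sum
## to one (mass conservation under zero padding, used for post-filters and
## scatter smoothing); "row" keeps the symmetric kernel rows (self-adjoint up
## to edge truncation, used in the projector PSF).
gauss_conv_matrix <- function(n, sigma_vox, normalize = c("col", "row")) {
  normalize <- match.arg(normalize)
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ii <- j + offs
    ok <- ii >= 1 & ii <= n
    B[ii[ok], j] <- k[ok]
  }
  if (normalize == "col") B <- sweep(B, 2, colSums(B), "/")
  B
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## separable 3D Gaussian blur, mass-conserving
gaussian_blur_3d <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3L)
  if (all(sigma_mm <= 0)) return(arr)
  Bs <- lapply(1:3, function(ax) gauss_conv_matrix(d[ax], sigma_mm[ax] / spacing[ax]))
  # contract along axis 1
  m <- matrix(arr, d[1], d[2] * d[3])
  m <- Bs[[1]] %*% m
  arr <- array(m, d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[2], d[1] * d[3])
  m <- Bs[[2]] %*% m
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  m <- matrix(arr, d[3], d[1] * d[2])
  m <- Bs[[3]] %*% m
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are exchanged in NIfTI-1 format with the grid spacing stored in
#' `pixdim`. Label volumes round-trip as integers.
#'
#' @param vol A `voxel_volume`.
#' @param path File path, conventionally ending in `.nii` or `.nii.gz`.
#' @param units Unit tag to attach on read.
#' @return `read_volume` returns a `voxel_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = "") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  voxel_volume(arr, spacing = RNifti::pixdim(img)[1:3], units = units)
}
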