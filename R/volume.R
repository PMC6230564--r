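#' 3D scalar volume with physical voxel spacing
#'
#' The basic carrier for T1-weighted, T2-weighted, bias, depth and ratio
#' images: a numeric 3D array plus a per-axis voxel size in millimetres.
#' Axes follow a fixed RAS convention with the world origin at voxel
#' `(1,1,1)`; no oblique orientations are represented.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size along each axis in mm; all
#'   strictly positive.
#' @param allow_na logical; if `FALSE` (default) all values must be finite.
#'   Ratio images use `NA` as the missing-value marker for excluded voxels
#'   and are built with `allow_na = TRUE`.
#' @return An object of class `scalar_volume` with elements `data` and
#'   `spacing`.
#' @examples
#' v <- scalar_volume(array(1, c(4, 4, 4)), spacing = c(1, 1, 1.2))
#' dim(v)
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), allow_na = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes (mm)", call. = FALSE)
  if (!allow_na && any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (allow_na && any(is.infinite(data)))
    stop("volume contains infinite values", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "scalar_volume")
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g], %d NA voxels\n",
              rng[1], rng[2], sum(is.na(x$data))))
  invisible(x)
}

#' @rdname scalar_volume
#' @param x object to coerce/test.
#' @export
is_scalar_volume <- function(x) inherits(x, "scalar_volume")

# internal: build a volume on the same grid as `vol`
vol_like <- function(vol, data, allow_na = TRUE) {
  scalar_volume(data, vol$spacing, allow_na = allow_na)
}

# internal: accept scalar_volume or bare array
as_vol_array <- function(x) {
  if (is_scalar_volume(x)) x$data else x
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(as_vol_array(a)), dim(as_vol_array(b))))
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry voxel spacing between the NIfTI header and [scalar_volume()].
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [scalar_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  sp <- RNifti::pixdim(img)[seq_len(3)]
  scalar_volume(arr, sp, allow_na = TRUE)
}

#' @rdname read_volume
#' @param vol a [scalar_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_scalar_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a binary mask bound to a source grid
#'
#' @param mask logical 3D array.
#' @param provenance one of `"head"`, `"cerebrum"`, `"GM"`, `"WM"`, `"shell"`,
#'   `"other"`: which stage produced the mask.
#' @return logical array of class `binary_mask` with a `provenance` attribute.
#' @export
binary_mask <- function(mask, provenance = "other") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim(mask))
  if (any(is.na(mask))) stop("mask contains NA", call. = FALSE)
  structure(mask, class = c("binary_mask", "array"), provenance = provenance)
}

as_mask_array <- function(x) {
  if (is_scalar_volume(x)) return(x$data > 0)
  if (is.logical(x)) return(x)
  x > 0
}
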