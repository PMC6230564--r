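#' Square-root-product bias field estimate
#'
#' The residual multiplicative bias common to the two contrasts is estimated
#' from the square root of the product of the T1w and T2w images inside the
#' cerebrum mask: the tissue contrasts are approximately inverted between
#' the two images, so their product varies mostly with the bias. The map is
#' normalized to unit mean within the mask, then smoothed with a Gaussian
#' kernel of standard deviation `sigma_mm` (5 mm default, taken literally as
#' a standard deviation rather than FWHM) confined to the mask with
#' renormalized weights, floored for positivity, and renormalized so the
#' in-mask mean is exactly 1.
#'
#' @param t1,t2 co-registered nonnegative [scalar_volume()]s.
#' @param cerebrum logical array (the cerebrum mask), at least 100 voxels.
#' @param sigma_mm Gaussian standard deviation in mm.
#' @return object of class `bias_field`: `field` ([scalar_volume()], `NA`
#'   outside the mask), `mask`, `sigma_mm`, `n_floored`.
#' @export
estimate_bias_field <- function(t1, t2, cerebrum, sigma_mm = 5) {
  stopifnot(is_scalar_volume(t1), is_scalar_volume(t2))
  check_same_grid(t1, t2)
  mask <- as_mask_array(cerebrum)
  check_same_grid(t1, mask, "volumes and mask")
  if (sum(mask) < 100)
    stop("insufficient-support: cerebrum mask below 100 voxels", call. = FALSE)
  if (any(t1$data[mask] < 0) || any(t2$data[mask] < 0))
    stop("negative intensities in mask", call. = FALSE)
  raw <- sqrt(t1$data * t2$data)
  raw[!mask] <- 0
  mu <- mean(raw[mask])
  if (mu <= 0) stop("degenerate images: zero mean product", call. = FALSE)
  f <- raw / mu
  sm <- masked_smooth(f, mask, sigma_mm, t1$spacing)
  floor_val <- 1e-3
  n_floored <- sum(sm[mask] < floor_val)
  sm[mask] <- pmax(sm[mask], floor_val)
  sm[mask] <- sm[mask] / mean(sm[mask])   # enforce unit in-mask mean
  structure(list(field = scalar_volume(sm, t1$spacing, allow_na = TRUE),
                 mask = mask, sigma_mm = sigma_mm, n_floored = n_floored),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  rng <- range(x$field$data[x$mask])
  cat(sprintf("<bias_field> sigma %.3g mm, in-mask range [%.4g, %.4g], mean %.6f\n",
              x$sigma_mm, rng[1], rng[2], mean(x$field$data[x$mask])))
  invisible(x)
}

#' Divide an image by a bias field
#'
#' Voxelwise division inside the field's mask; voxels outside the mask are
#' returned unchanged and flagged in the `corrected` attribute.
#'
#' @param vol a [scalar_volume()] on the field's grid.
#' @param field a `bias_field` from [estimate_bias_field()].
#' @return corrected [scalar_volume()] with a logical `corrected` attribute.
#' @export
correct_bias <- function(vol, field) {
  stopifnot(is_scalar_volume(vol), inherits(field, "bias_field"))
  check_same_grid(vol, field$field, "volume and field")
  out <- vol$data
  m <- field$mask
  out[m] <- out[m] / field$field$data[m]
  res <- vol_like(vol, out, allow_na = TRUE)
  attr(res, "corrected") <- m
  res
}

#' Corrected T1w/T2w ratio image
#'
#' Voxelwise division of the corrected T1w by the corrected T2w inside the
#' mask. Voxels whose T2w denominator falls at or below a quantile-based
#' floor carry the missing-value marker (`NA`) and are omitted from all
#' downstream means. More than 20 percent of the mask excluded is a quality
#' error.
#'
#' @param t1c,t2c bias-corrected [scalar_volume()]s.
#' @param mask logical array over which the ratio is defined.
#' @param floor_quantile denominator floor as a quantile of in-mask T2w
#'   (default 1st percentile).
#' @return ratio [scalar_volume()] (`NA` outside mask and at excluded
#'   voxels) with attribute `n_excluded`.
#' @export
compute_ratio <- function(t1c, t2c, mask, floor_quantile = 0.01) {
  stopifnot(is_scalar_volume(t1c), is_scalar_volume(t2c))
  check_same_grid(t1c, t2c)
  mask <- as_mask_array(mask)
  check_same_grid(t1c, mask, "volumes and mask")
  floor_val <- quantile(t2c$data[mask], floor_quantile, na.rm = TRUE)
  ok <- mask & !is.na(t2c$data) & !is.na(t1c$data) & t2c$data > floor_val
  n_excl <- sum(mask) - sum(ok)
  if (n_excl > 0.2 * sum(mask))
    stop(sprintf("quality error: %.1f%% of mask excluded by the denominator floor",
                 100 * n_excl / sum(mask)), call. = FALSE)
  out <- array(NA_real_, dim(mask))
  out[ok] <- t1c$data[ok] / t2c$data[ok]
  res <- vol_like(t1c, out, allow_na = TRUE)
  attr(res, "n_excluded") <- n_excl
  res
}
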