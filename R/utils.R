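# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a Gaussian FWHM to a standard deviation
#'
#' Neuroimaging smoothing kernels are conventionally quoted as full width at
#' half maximum; `sigma = fwhm / (2 sqrt(2 log 2)) ~ fwhm / 2.355`.
#'
#' @param fwhm full width at half maximum (mm).
#' @return standard deviation in the same units.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1D Gaussian kernel in voxel units, truncated at `trunc` sigma.
gaussian_kernel_1d <- function(sigma_vox, trunc = 3) {
  r <- max(1L, as.integer(ceiling(trunc * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable 3D Gaussian smoothing; sigma in mm, converted per axis.
smooth_gaussian <- function(arr, sigma_mm, spacing, trunc = 3) {
  ks <- lapply(1:3, function(a) gaussian_kernel_1d(sigma_mm / spacing[a], trunc))
  cpp_conv3d_sep(arr, ks[[1]], ks[[2]], ks[[3]])
}

# Mask-confined smoothing: smooth(v * m) / smooth(m). Weights are the 3D
# Gaussian in physical distance, renormalized over in-mask neighbours, so
# constants are preserved and nothing leaks across the mask boundary.
masked_smooth <- function(arr, mask, sigma_mm, spacing, trunc = 3) {
  m <- array(as.numeric(mask), dim(arr))
  v <- arr
  v[!mask] <- 0
  num <- smooth_gaussian(v, sigma_mm, spacing, trunc)
  den <- smooth_gaussian(m, sigma_mm, spacing, trunc)
  out <- array(NA_real_, dim(arr))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# Shift a 3D array by one voxel along an axis, padding with `fill`.
shift1 <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (by + 1):d[axis]
    src[[axis]] <- 1:(d[axis] - by)
  } else {
    dst[[axis]] <- 1:(d[axis] + by)
    src[[axis]] <- (1 - by):d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Morphology with the 6-connectivity cross element (3x3x3 ball of radius 1 in
# the city-block metric), one iteration. Out-of-grid neighbours count as
# background for dilation and as foreground for erosion (padding-neutral).
dilate6 <- function(mask) {
  out <- cpp_morph6(mask, 1L)
  array(out, dim(mask))
}

erode6 <- function(mask) {
  out <- cpp_morph6(mask, 0L)
  array(out, dim(mask))
}

# Two-class maximum-between-class-variance intensity split (histogram based).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

largest_component <- function(mask, connectivity = 6L) {
  lab <- cpp_cc_label(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(mask))
}

# 26-neighbourhood adjacency test: does any voxel of `a` touch `b`?
touches26 <- function(a, b) {
  grown <- a
  for (ax in 1:3) for (s in c(-1L, 1L)) grown <- grown | shift1(grown, ax, s, FALSE)
  any(grown & b)
}

# Draw a sub-2^31 integer seed stream deterministically from a master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(2^31 - 1, n)
}
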