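#' Local intensity normalization of a T1w image
#'
#' Slides a cubic maximum filter (default 3x3x3) across the image, smooths
#' the result with a 3D Gaussian kernel (default 10 mm, read as FWHM per
#' neuroimaging convention) to form an intensity field map, and divides the
#' original image by that map. The output is dimensionless, predominantly in
#' (0, 1], and flattens slow multiplicative bias so the pial surface
#' segments reliably. It is meant for masking and segmentation only - never
#' for the ratio analysis itself, which consumes original intensities.
#'
#' A division floor at 5 percent of the field median prevents blow-up in the
#' background; floored voxels are flagged in the `floored` attribute and
#' should be excluded from masks. When a head mask is supplied, the field
#' smoothing is confined to it with renormalized weights, so the empty
#' background cannot drag the intensity envelope down at the pial surface
#' (the same guard philosophy as the division floor; on whole-head images
#' with scalp signal the unmasked and masked variants agree closely).
#'
#' @param t1 nonnegative [scalar_volume()].
#' @param window odd cubic window width in voxels for the max filter.
#' @param smooth_fwhm Gaussian FWHM in mm.
#' @param mask optional logical array confining the field smoothing (e.g.
#'   the head mask); outside it the field is held at its in-mask maximum.
#' @return dimensionless [scalar_volume()] with a logical `floored`
#'   attribute.
#' @export
local_intensity_normalize <- function(t1, window = 3L, smooth_fwhm = 10,
                                      mask = NULL) {
  stopifnot(is_scalar_volume(t1))
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (any(t1$data < 0)) stop("T1w intensities must be nonnegative", call. = FALSE)
  if (all(t1$data == 0)) stop("degenerate-input: all-zero image", call. = FALSE)
  mf <- cpp_maxfilter3(t1$data, (window - 1L) %/% 2L)
  sig <- fwhm_to_sigma(smooth_fwhm)
  if (is.null(mask)) {
    # renormalized at the grid boundary so a constant image maps to exactly 1
    fld <- masked_smooth(mf, array(TRUE, dim(mf)), sig, t1$spacing)
  } else {
    mask <- as_mask_array(mask)
    check_same_grid(t1, mask, "image and mask")
    fld <- masked_smooth(mf, mask, sig, t1$spacing)
    fld[!mask] <- max(fld[mask])
  }
  floor_val <- 0.05 * median(fld)
  floored <- fld < floor_val
  fld[floored] <- floor_val
  out <- vol_like(t1, t1$data / fld, allow_na = FALSE)
  attr(out, "floored") <- floored
  out
}

#' Histogram-based CSF threshold
#'
#' Smooths the intensity histogram with a Gaussian kernel density estimate
#' and places the threshold at the deepest local minimum between the darkest
#' mode (CSF/background) and the next mode (grey matter). If the smoothed
#' histogram has no interior minimum (unimodal input), falls back to the
#' two-class variance-maximizing split and sets a warning flag.
#'
#' @param intensities numeric vector of (normalized) intensities inside the
#'   head mask; at least 1000 voxels.
#' @param bw_adjust bandwidth multiplier handed to [stats::density()].
#' @return list: `threshold`, `method` (`"valley"` or `"otsu"`), `unimodal`.
#' @export
estimate_csf_threshold <- function(intensities, bw_adjust = 1) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 1000)
    stop("need at least 1000 voxels to estimate a threshold", call. = FALSE)
  d <- density(x, n = 512, adjust = bw_adjust)
  y <- d$y
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > 0.02 * max(y)
  peaks <- which(is_max)
  # merge plateau-adjacent peaks
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 3)]
  if (length(peaks) >= 2) {
    i1 <- peaks[1]; i2 <- peaks[2]
    seg <- seq(i1, i2)
    imin <- seg[which.min(y[seg])]
    if (imin > i1 && imin < i2)
      return(list(threshold = d$x[imin], method = "valley", unimodal = FALSE))
  }
  warning("unimodal intensity histogram; falling back to a variance-maximizing split")
  list(threshold = otsu_threshold(x), method = "otsu", unimodal = TRUE)
}

#' Options for cerebrum mask construction
#'
#' @param sharpen_amount unsharp-mask amount (1 adds the full high-pass
#'   residual).
#' @param sharpen_radius unsharp-mask Gaussian sigma in voxels (at the
#'   upsampled resolution).
#' @param min_component_voxels connected components smaller than this (at the
#'   upsampled resolution) are removed before morphology.
#' @param morph_iterations erosions, then the same number of dilations, with
#'   a 3x3x3 cross (6-connectivity ball) element.
#' @export
skull_strip_options <- function(sharpen_amount = 1, sharpen_radius = 1,
                                min_component_voxels = 100,
                                morph_iterations = 1L) {
  list(sharpen_amount = sharpen_amount, sharpen_radius = sharpen_radius,
       min_component_voxels = min_component_voxels,
       morph_iterations = morph_iterations)
}

#' Cerebrum mask from a normalized T1w image
#'
#' Fixed pipeline: mask with the head mask, double the resolution in all
#' dimensions (linear), unsharp-mask sharpen to steepen the pial gradient,
#' apply the CSF threshold, remove small connected components, erode then
#' dilate with the same structuring element (removing thin dura), downsample
#' to the original grid, and re-apply the same CSF threshold to strip CSF
#' re-admitted by the dilation. The largest remaining connected component is
#' returned.
#'
#' @param norm_t1 locally normalized T1w ([local_intensity_normalize()]).
#' @param head_mask logical array covering brain plus dura.
#' @param threshold CSF threshold on normalized intensities; when `NULL` it
#'   is estimated from the head-mask voxels via [estimate_csf_threshold()].
#' @param opts a [skull_strip_options()] list.
#' @return a cerebrum [binary_mask()] with attributes `threshold` and
#'   `threshold_method`.
#' @export
skull_strip <- function(norm_t1, head_mask, threshold = NULL,
                        opts = skull_strip_options()) {
  stopifnot(is_scalar_volume(norm_t1))
  head_mask <- as_mask_array(head_mask)
  check_same_grid(norm_t1, head_mask, "image and head mask")
  method <- "given"
  if (is.null(threshold)) {
    est <- estimate_csf_threshold(norm_t1$data[head_mask])
    threshold <- est$threshold
    method <- est$method
  }
  floored <- attr(norm_t1, "floored")
  v <- norm_t1$data
  v[!head_mask] <- 0
  if (!is.null(floored)) v[floored] <- 0
  d <- dim(v)
  # upsample 2x: fine voxel i (0-based, spacing h/2) sits at input coord i/2
  A <- cbind(diag(0.5, 3), c(0, 0, 0))
  up <- cpp_resample_affine(array(v, d), as.integer(2L * d), A, 0L)$values
  if (opts$sharpen_amount > 0) {
    blur <- smooth_gaussian(up, opts$sharpen_radius * min(norm_t1$spacing) / 2,
                            norm_t1$spacing / 2)
    up <- up + opts$sharpen_amount * (up - blur)
  }
  m <- up > threshold
  lab <- cpp_cc_label(m, 6L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= opts$min_component_voxels)
    m <- array(lab %in% keep, dim(m))
  }
  for (i in seq_len(opts$morph_iterations)) m <- erode6(m)
  for (i in seq_len(opts$morph_iterations)) m <- dilate6(m)
  dn <- cpp_block_mean(array(as.numeric(m), dim(m)), 2L) >= 0.5
  out <- dn & (norm_t1$data > threshold) & head_mask
  if (!is.null(floored)) out <- out & !floored
  if (!any(out)) stop("segmentation-failure: empty cerebrum mask", call. = FALSE)
  out <- largest_component(out, 6L)
  res <- binary_mask(out, "cerebrum")
  attr(res, "threshold") <- threshold
  attr(res, "threshold_method") <- method
  res
}

#' Spatially regularized fuzzy c-means tissue segmentation
#'
#' Alternating minimization of the fuzzy c-means objective augmented with a
#' 6-neighbour membership-smoothness penalty (weight `spatial_beta`; 0 gives
#' classic FCM). Centroids are initialized deterministically from intensity
#' quantiles of the masked voxels (25th/75th percentile for two classes);
#' `seed` only matters for the optional random initialization. Convergence
#' is declared when the largest centroid shift falls below `tol`.
#'
#' @param vol intensity [scalar_volume()] (typically the normalized T1w
#'   restricted to the cerebrum).
#' @param mask logical array of voxels to segment.
#' @param n_classes number of tissue classes (2: GM and WM).
#' @param m fuzziness exponent (> 1).
#' @param spatial_beta neighbourhood smoothness weight (>= 0).
#' @param tol centroid-shift convergence tolerance.
#' @param max_iter iteration cap.
#' @param init `"quantile"` (deterministic) or `"random"`.
#' @param seed used only for `init = "random"`.
#' @return object of class `membership_volume`: per-class membership arrays
#'   (`memberships`, ordered by increasing centroid so class 1 is GM and
#'   class 2 WM on normalized T1w), `centroids`, `hard_labels` (0 outside
#'   mask, 1..K inside), `objective` trace, `iterations`, `converged`.
#' @export
fuzzy_segment <- function(vol, mask, n_classes = 2L, m = 2, spatial_beta = 0,
                          tol = 1e-4, max_iter = 200L,
                          init = c("quantile", "random"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(is_scalar_volume(vol), m > 1, spatial_beta >= 0)
  mask <- as_mask_array(mask)
  check_same_grid(vol, mask, "image and mask")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  x <- vol$data[mask]
  if (any(!is.finite(x))) stop("non-finite intensities in mask", call. = FALSE)
  if (length(unique(x)) < n_classes)
    stop("degenerate-input: fewer distinct intensities than classes", call. = FALSE)
  cen0 <- if (init == "quantile") {
    as.numeric(quantile(x, (seq_len(n_classes) - 0.5) / n_classes))
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sort(sample(x, n_classes))
  }
  if (anyDuplicated(cen0)) cen0 <- cen0 + seq_len(n_classes) * 1e-6 * max(abs(x), 1)
  fit <- cpp_fcm(vol$data, mask, cen0, m, spatial_beta, tol, as.integer(max_iter))
  ord <- order(fit$centroids)
  mem <- fit$memberships[ord]
  cen <- fit$centroids[ord]
  stacked <- vapply(mem, function(a) a[mask], numeric(sum(mask)))
  hard <- array(0L, dim(vol$data))
  hard[mask] <- max.col(stacked, ties.method = "first")
  structure(list(memberships = mem, centroids = cen, hard_labels = hard,
                 mask = mask, objective = fit$objective,
                 iterations = fit$iterations, converged = fit$converged,
                 m = m, spatial_beta = spatial_beta),
            class = "membership_volume")
}

#' @export
print.membership_volume <- function(x, ...) {
  cat(sprintf("<membership_volume> %d classes, centroids %s, %d iterations (%s)\n",
              length(x$centroids), paste(signif(x$centroids, 5), collapse = ", "),
              x$iterations, if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Dice overlap between two masks
#'
#' `2|A & B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical arrays.
#' @export
dice <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}
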