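#' Resample a volume through a rigid transform onto a reference grid
#'
#' The transform maps reference-space coordinates to moving-space coordinates
#' (the "pull" convention): the output value at reference voxel `x` is the
#' moving volume interpolated at `T(x)`. Out-of-fov voxels are set to 0 and
#' flagged `FALSE` in the `valid` attribute.
#'
#' @param vol the moving [scalar_volume()].
#' @param transform a [rigid_transform()]; identity by default.
#' @param reference [scalar_volume()] whose grid defines the output; defaults
#'   to `vol`'s own grid.
#' @param interpolation `"linear"` (trilinear) or `"nearest"` (for label
#'   volumes).
#' @return A [scalar_volume()] on the reference grid, with a logical `valid`
#'   attribute marking in-fov voxels.
#' @export
resample <- function(vol, transform = rigid_transform(), reference = vol,
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_scalar_volume(vol))
  M <- rt_matrix(transform)
  if (any(!is.finite(M))) stop("transform is not finite", call. = FALSE)
  # output voxel (0-based) -> mm -> transform -> mm -> input voxel (0-based)
  S_ref <- diag(reference$spacing)
  S_in_inv <- diag(1 / vol$spacing)
  A <- matrix(0, 3, 4)
  A[, 1:3] <- S_in_inv %*% M[1:3, 1:3] %*% S_ref
  A[, 4] <- S_in_inv %*% M[1:3, 4]
  res <- cpp_resample_affine(vol$data, dim(reference$data), A,
                             if (interpolation == "nearest") 1L else 0L)
  out <- scalar_volume(res$values, reference$spacing, allow_na = TRUE)
  attr(out, "valid") <- res$valid
  out
}

# Normalized cross-correlation between two intensity vectors.
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Central-difference gradient magnitude (per mm). Registration correlates
# gradient magnitudes rather than raw intensities: tissue interfaces light
# up in both contrasts regardless of polarity, so the metric peaks at
# alignment for T2w-to-T1w (inverted-contrast) pairs as well as
# same-contrast pairs, at every pyramid level.
grad_mag <- function(vol) {
  a <- vol$data
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    d <- (shift1(a, ax, -1, NA) - shift1(a, ax, 1, NA)) / (2 * vol$spacing[ax])
    d[is.na(d)] <- 0
    g2 <- g2 + d^2
  }
  scalar_volume(sqrt(g2), vol$spacing)
}

# Block-mean pyramid level of a volume (factor >= 1 integer).
downsample_vol <- function(vol, f) {
  if (f == 1) return(vol)
  scalar_volume(cpp_block_mean(vol$data, as.integer(f)), vol$spacing * f)
}

#' Options for rigid registration
#'
#' @param levels integer downsampling factors of the multi-resolution pyramid,
#'   coarse to fine. The finest level listed is where the optimum is polished;
#'   `c(4, 2, 1)` works at full resolution, `c(4, 2)` stops at half
#'   resolution (faster, adequate for sub-voxel offsets).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param reltol relative convergence tolerance of the simplex at the finest
#'   level (coarser levels use `1e-6`).
#' @param foreground_quantile intensity quantile of the fixed image used to
#'   define the foreground over which the metric is computed; `NULL`
#'   (default) uses a two-class variance-maximizing split instead, which
#'   separates head from background without tuning.
#' @param init_search_mm half-width of the exhaustive translation search at
#'   the coarsest level (steps of one coarse voxel) that seeds the simplex
#'   inside the correct basin of attraction; 0 disables it.
#' @export
registration_options <- function(levels = c(4, 2, 1), maxit = 1000,
                                 reltol = 1e-8, foreground_quantile = NULL,
                                 init_search_mm = 8) {
  list(levels = levels, maxit = maxit, reltol = reltol,
       foreground_quantile = foreground_quantile,
       init_search_mm = init_search_mm)
}

#' Rigid intra-subject registration by normalized cross-correlation
#'
#' Recovers the 6-parameter rigid transform aligning `moving` onto `fixed`
#' by maximizing normalized cross-correlation between the two images'
#' gradient magnitudes, with a coarse-to-fine multi-resolution Nelder-Mead
#' search seeded by an exhaustive translation scan at the coarsest level.
#' Correlating gradient magnitudes instead of raw intensities makes the
#' metric insensitive to contrast polarity, so the same estimator aligns
#' inverted-contrast T2w-to-T1w pairs and same-contrast pairs. The rotation
#' centre is the centre of mass of the fixed foreground, which decorrelates
#' rotation and translation parameters.
#'
#' The returned transform is in the pull convention of [resample()]:
#' `resample(moving, transform, reference = fixed)` produces the aligned
#' volume.
#'
#' @param moving,fixed [scalar_volume()] objects with overlapping anatomy.
#' @param opts a [registration_options()] list.
#' @return A list of class `rigid_registration`: `transform`
#'   ([rigid_transform()]), `metric` (NCC at the optimum), `metric_initial`,
#'   `converged`, `evaluations`.
#' @export
rigid_register <- function(moving, fixed, opts = registration_options()) {
  stopifnot(is_scalar_volume(moving), is_scalar_volume(fixed))
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stop("cannot register constant images", call. = FALSE)

  thr <- if (is.null(opts$foreground_quantile)) otsu_threshold(fixed$data)
         else quantile(fixed$data, opts$foreground_quantile)
  fg <- fixed$data > thr
  if (!any(fg)) stop("empty fixed-image foreground", call. = FALSE)
  idx <- which(fg, arr.ind = TRUE)
  com <- colMeans((idx - 1) * rep(fixed$spacing, each = nrow(idx)))

  eval_count <- 0L
  # lean metric evaluation: builds the voxel-to-voxel affine directly and
  # evaluates resampling + NCC in one fused pass, since this runs hundreds
  # of times per registration
  objective <- function(par, fx, mv) {
    eval_count <<- eval_count + 1L
    R <- rot_matrix(par[1:3])
    d <- as.numeric(-R %*% com + com + par[4:6])
    A <- matrix(0, 3, 4)
    A[, 1:3] <- (R * rep(fx$spacing, each = 3)) / mv$spacing
    A[, 4] <- d / mv$spacing
    -cpp_ncc_affine(fx$data, mv$data, A)
  }

  par <- c(0, 0, 0, 0, 0, 0)
  metric_initial <- NA_real_
  conv <- 0L
  nlev <- length(opts$levels)
  for (li in seq_len(nlev)) {
    f <- opts$levels[li]
    fx <- grad_mag(downsample_vol(fixed, f))
    mv <- grad_mag(downsample_vol(moving, f))
    if (li == nlev)   # metric at the identity, on the level the result uses
      metric_initial <- -objective(numeric(6), fx, mv)
    if (li == 1) {
      if (opts$init_search_mm > 0) {
        step <- max(fx$spacing)
        offs <- seq(-opts$init_search_mm, opts$init_search_mm, by = step)
        best <- objective(par, fx, mv)
        for (tx in offs) for (ty in offs) for (tz in offs) {
          v <- objective(c(0, 0, 0, tx, ty, tz), fx, mv)
          if (v < best) { best <- v; par[4:6] <- c(tx, ty, tz) }
        }
      }
    }
    rt <- if (li == nlev) opts$reltol else 1e-6
    # parscale 10 gives the simplex initial steps of ~1 mm / 1 deg, matching
    # the offsets being sought; raw 0.1-unit steps stall on flat terrain
    fit <- optim(par, objective, fx = fx, mv = mv,
                 method = "Nelder-Mead",
                 control = list(maxit = opts$maxit, reltol = rt,
                                parscale = rep(10, 6)))
    par <- fit$par
    conv <- fit$convergence
    if (conv != 0L) {
      # restart once with a fresh simplex: Nelder-Mead simplices can collapse
      # into a degenerate shape and stall short of the tolerance
      fit <- optim(par, objective, fx = fx, mv = mv,
                   method = "Nelder-Mead",
                   control = list(maxit = opts$maxit, reltol = rt,
                                  parscale = rep(10, 6)))
      par <- fit$par
      conv <- fit$convergence
    }
  }
  result <- list(transform = rigid_transform(par[1:3], par[4:6], com),
                 metric = -fit$value, metric_initial = metric_initial,
                 converged = conv == 0L, evaluations = eval_count)
  class(result) <- "rigid_registration"
  if (conv != 0L) {
    cond <- structure(class = c("cortexratio_registration_failure", "error",
                                "condition"),
                      list(message = "rigid registration hit the iteration cap before converging",
                           call = sys.call(-1), best = result))
    stop(cond)
  }
  result
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat("<rigid_registration>\n  NCC:", signif(x$metric, 6),
      "(initial", paste0(signif(x$metric_initial, 6), ")"),
      "\n  evaluations:", x$evaluations, "\n")
  print(x$transform)
  invisible(x)
}
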