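#' Normalized cortical depth by Laplace's equation
#'
#' Solves the Laplace equation over the grey-matter ribbon with Dirichlet
#' conditions 0 on the white-matter side and 1 on the CSF/outside side, by
#' red-black Gauss-Seidel relaxation of the 6-neighbour Laplacian (weights
#' scaled by squared voxel spacings for anisotropic grids). By the discrete
#' maximum principle the interior solution lies strictly inside (0, 1).
#'
#' @param gm_mask logical array: the cortical ribbon (free voxels).
#' @param wm_mask logical array: white matter (depth 0 boundary).
#' @param outside_mask logical array: CSF/background (depth 1 boundary);
#'   defaults to everything that is neither GM nor WM.
#' @param spacing voxel size in mm.
#' @param tol maximum per-sweep update below which iteration stops.
#' @param max_iter sweep cap.
#' @param on_topology what to do with ribbon components that do not touch
#'   both boundaries: `"error"` (default, listing offending voxels) or
#'   `"drop"` (remove them from the ribbon, recording the count).
#' @return object of class `depth_map`: `depth` (array, `NA` off-ribbon),
#'   `gm_mask`, `iterations`, `converged`, `dropped` (voxels removed under
#'   `on_topology = "drop"`), `spacing`.
#' @export
solve_laplace_depth <- function(gm_mask, wm_mask, outside_mask = NULL,
                                spacing = c(1, 1, 1), tol = 1e-5,
                                max_iter = 5000L,
                                on_topology = c("error", "drop")) {
  on_topology <- match.arg(on_topology)
  gm <- as_mask_array(gm_mask); wm <- as_mask_array(wm_mask)
  check_same_grid(gm, wm, "masks")
  if (is.null(outside_mask)) outside_mask <- !(gm | wm)
  out <- as_mask_array(outside_mask)
  if (!any(gm)) stop("empty ribbon", call. = FALSE)
  if (!any(wm) || !any(out)) stop("both boundaries must be nonempty", call. = FALSE)
  gm <- gm & !wm

  # every ribbon component must reach both boundaries
  lab <- cpp_cc_label(gm, 6L)
  ncomp <- max(lab)
  dropped <- 0L
  if (ncomp > 0) {
    wm_adj <- out_adj <- rep(FALSE, ncomp)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      lw <- lab[shift1(wm, ax, s, FALSE) & gm]
      lo <- lab[shift1(out, ax, s, FALSE) & gm]
      wm_adj[unique(lw[lw > 0])] <- TRUE
      out_adj[unique(lo[lo > 0])] <- TRUE
    }
    bad <- which(!(wm_adj & out_adj))
    if (length(bad) > 0) {
      if (on_topology == "error") {
        vox <- which(array(lab %in% bad, dim(gm)))
        stop(sprintf("topology error: %d ribbon voxels have no path to both boundaries (first indices: %s)",
                     length(vox), paste(head(vox, 10), collapse = ", ")),
             call. = FALSE)
      }
      drop_sel <- array(lab %in% bad, dim(gm))
      dropped <- sum(drop_sel)
      gm <- gm & !drop_sel
      if (!any(gm)) stop("empty ribbon after dropping disconnected voxels", call. = FALSE)
    }
  }

  code <- array(0L, dim(gm))
  code[gm] <- 1L
  init <- array(1, dim(gm))   # non-ribbon, non-WM voxels carry the outer value
  init[wm] <- 0
  init[gm] <- 0.5
  sol <- cpp_laplace_gs(code, init, spacing, tol, as.integer(max_iter))
  depth <- array(NA_real_, dim(gm))
  depth[gm] <- sol$solution[gm]
  structure(list(depth = depth, gm_mask = gm, iterations = sol$iterations,
                 converged = sol$converged, dropped = dropped,
                 spacing = spacing),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d ribbon voxels, %d sweeps (%s)%s\n",
              sum(x$gm_mask), x$iterations,
              if (x$converged) "converged" else "cap reached",
              if (x$dropped > 0) sprintf(", %d voxels dropped", x$dropped) else ""))
  invisible(x)
}

#' Volume-preserving (equivolume) depth reparameterization
#'
#' Reparameterizes the harmonic depth so that equal depth fractions enclose
#' equal local tissue volume between the two surfaces. With local boundary
#' area proxies `A_in` (white surface) and `A_out` (pial surface), and
#' cross-sectional area assumed linear in depth, the cumulative-volume
#' fraction is
#' `f(d) = (2 A_in d + (A_out - A_in) d^2) / (A_in + A_out)`,
#' which reduces to the identity when the areas are equal (flat cortex) and
#' is strictly increasing for positive areas. Where the cortex bulges
#' outward (`A_out > A_in`), volume accumulates faster near the pial side,
#' so the surface enclosing half the local volume sits farther from the
#' white surface than the equidistant midpoint (on a spherical shell the
#' half-volume radius is `((a^3 + b^3)/2)^(1/3)`, beyond the mid radius).
#'
#' @param depth a `depth_map`.
#' @param inner_area_proxy,outer_area_proxy positive scalars or arrays on
#'   the same grid; see [estimate_area_proxies()] for a global estimate.
#' @return a `depth_map` with reparameterized values (attribute
#'   `equivolume = TRUE`). Degenerate (nonpositive/non-finite) proxies fall
#'   back to the unadjusted depth with a warning.
#' @export
equivolume_fraction <- function(depth, inner_area_proxy, outer_area_proxy) {
  stopifnot(inherits(depth, "depth_map"))
  gm <- depth$gm_mask
  ain <- if (length(inner_area_proxy) == 1) rep(inner_area_proxy, sum(gm)) else as_vol_array(inner_area_proxy)[gm]
  aout <- if (length(outer_area_proxy) == 1) rep(outer_area_proxy, sum(gm)) else as_vol_array(outer_area_proxy)[gm]
  if (any(!is.finite(ain)) || any(!is.finite(aout)) ||
      any(ain <= 0) || any(aout <= 0)) {
    warning("degenerate area proxy; returning unadjusted depth")
    return(depth)
  }
  d <- depth$depth[gm]
  f <- (2 * ain * d + (aout - ain) * d^2) / (ain + aout)
  out <- depth
  out$depth[gm] <- f
  attr(out, "equivolume") <- TRUE
  out
}

#' Global boundary-area proxies from interface face counts
#'
#' Counts grid faces between the ribbon and each boundary (weighted by the
#' physical face area) as a global proxy for the white and pial surface
#' areas. Adequate for closed phantom geometries; for per-streamline
#' correction supply voxelwise proxy maps to [equivolume_fraction()]
#' instead.
#'
#' @param gm_mask,wm_mask,outside_mask logical arrays.
#' @param spacing voxel size in mm.
#' @return list `inner`, `outer` (mm^2).
#' @export
estimate_area_proxies <- function(gm_mask, wm_mask, outside_mask = NULL,
                                  spacing = c(1, 1, 1)) {
  gm <- as_mask_array(gm_mask); wm <- as_mask_array(wm_mask)
  if (is.null(outside_mask)) outside_mask <- !(gm | wm)
  out <- as_mask_array(outside_mask)
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  inner <- outer <- 0
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    inner <- inner + face[ax] * sum(gm & shift1(wm, ax, s, FALSE))
    outer <- outer + face[ax] * sum(gm & shift1(out, ax, s, FALSE))
  }
  list(inner = inner, outer = outer)
}

#' Extract the mid-depth shell and carry ROI labels onto it
#'
#' The volumetric stand-in for a mid-depth cortical surface: ribbon voxels
#' with normalized depth within `band_halfwidth` of 0.5. ROI identifiers are
#' copied voxelwise from the supplied label volume (ground-truth label
#' transfer replaces surface-mesh registration for phantoms).
#'
#' @param depth a `depth_map`.
#' @param band_halfwidth half-width `w` of the depth band; the shell is
#'   `|depth - 0.5| <= w` (so `w = 0.5` returns the whole ribbon).
#' @param roi_labels integer array, 0 outside GM, 1..R inside.
#' @return object of class `middepth_shell`: `mask`, `roi` (integer array),
#'   `band_halfwidth`, `n_voxels`.
#' @export
extract_middepth_shell <- function(depth, band_halfwidth = 0.1, roi_labels) {
  stopifnot(inherits(depth, "depth_map"), band_halfwidth > 0)
  check_same_grid(depth$depth, roi_labels, "depth and ROI labels")
  shell <- depth$gm_mask & !is.na(depth$depth) &
    abs(depth$depth - 0.5) <= band_halfwidth
  if (!any(shell))
    stop("band-too-narrow: empty mid-depth shell", call. = FALSE)
  roi <- array(0L, dim(shell))
  roi[shell] <- as.integer(roi_labels[shell])
  structure(list(mask = binary_mask(shell, "shell"), roi = roi,
                 band_halfwidth = band_halfwidth, n_voxels = sum(shell),
                 spacing = depth$spacing),
            class = "middepth_shell")
}

#' @export
print.middepth_shell <- function(x, ...) {
  cat(sprintf("<middepth_shell> %d voxels, band halfwidth %.3g, %d ROIs present\n",
              x$n_voxels, x$band_halfwidth, length(unique(x$roi[x$mask]))))
  invisible(x)
}

#' Gaussian smoothing restricted to the mid-depth shell
#'
#' Smooths values over shell voxels with weights given by the 3D Gaussian of
#' physical distance (support truncated at 3 sigma), renormalized over
#' in-shell neighbours only, so nothing leaks across CSF or WM and constant
#' fields are preserved exactly. `NA` values (excluded voxels) neither
#' receive nor contribute weight. Isolated shell voxels keep their value and
#' are counted in the `isolated` attribute.
#'
#' @param values numeric array on the full grid (e.g. a ratio image).
#' @param shell a `middepth_shell`.
#' @param fwhm smoothing kernel FWHM in mm.
#' @return numeric array: smoothed values on shell voxels, `NA` elsewhere,
#'   with an `isolated` attribute.
#' @export
smooth_on_shell <- function(values, shell, fwhm = 6) {
  stopifnot(inherits(shell, "middepth_shell"))
  values <- as_vol_array(values)
  check_same_grid(values, shell$mask, "values and shell")
  ok <- shell$mask & is.finite(values)
  sig <- fwhm_to_sigma(fwhm)
  v <- values; v[!ok] <- 0
  m <- array(as.numeric(ok), dim(values))
  num <- smooth_gaussian(v, sig, shell$spacing, trunc = 3)
  den <- smooth_gaussian(m, sig, shell$spacing, trunc = 3)
  out <- array(NA_real_, dim(values))
  out[ok] <- num[ok] / den[ok]
  # an isolated voxel's renormalized kernel collapses to itself
  self_w <- prod(vapply(1:3, function(a)
    max(gaussian_kernel_1d(sig / shell$spacing[a], 3)), numeric(1)))
  isolated <- sum(abs(den[ok] - self_w) < 1e-12)
  attr(out, "isolated") <- isolated
  out
}
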