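#' Phantom geometry parameters
#'
#' Nested-ellipsoid head geometry: a white-matter core, a cortical
#' grey-matter ribbon, a CSF gap, and a thin dura shell, with a sinusoidal
#' angular perturbation of all interfaces so the cortex has nonzero
#' curvature (the unperturbed limit admits closed-form checks).
#'
#' @param wm_radii numeric length-3, semi-axes of the WM core in mm.
#' @param gm_thickness cortical ribbon thickness in mm (radial).
#' @param csf_thickness CSF gap between pial surface and dura, mm.
#' @param dura_thickness dura shell thickness, mm; keep at or below one voxel
#'   so the morphological opening in skull stripping can remove it.
#' @param perturb_amp relative amplitude of the sinusoidal surface
#'   perturbation (0 = perfect ellipsoids). The default is pronounced:
#'   a nearly rotation-symmetric head leaves rigid rotation unidentifiable
#'   for any registration algorithm, so the phantom must carry angular
#'   structure the way a gyrified cortex does.
#' @param perturb_freq integer angular frequency of the perturbation.
#' @export
phantom_geometry <- function(wm_radii = c(14, 13, 12.5), gm_thickness = 4,
                             csf_thickness = 2, dura_thickness = 1,
                             perturb_amp = 0.12, perturb_freq = 4) {
  list(wm_radii = wm_radii, gm_thickness = gm_thickness,
       csf_thickness = csf_thickness, dura_thickness = dura_thickness,
       perturb_amp = perturb_amp, perturb_freq = perturb_freq)
}

#' Tissue intensity means for the two contrasts
#'
#' Piecewise-constant clean intensities per tissue. Defaults give the usual
#' orderings (T1w: WM > GM > CSF; T2w: CSF > GM > WM), hence a clean ratio
#' ordered WM > GM > CSF.
#'
#' @param t1,t2 named numeric vectors with entries `wm`, `gm`, `csf`, `dura`,
#'   `background`. Dura is bright on T1w (fat/vessel signal) and dark on
#'   T2w.
#' @export
phantom_tissue_means <- function(
    t1 = c(wm = 1.0, gm = 0.7, csf = 0.25, dura = 0.85, background = 0),
    t2 = c(wm = 0.5, gm = 0.8, csf = 1.3, dura = 0.4, background = 0)) {
  list(t1 = t1, t2 = t2)
}

# Region codes used internally (tissue labels conflate CSF and background as
# 0; intensities do not, so a finer region volume is kept in the truth).
REGION <- c(background = 0L, gm = 1L, wm = 2L, dura = 3L, csf = 4L)

# Partition the unit sphere into R roughly equal-area contiguous sectors:
# polar bands, each split into a number of azimuthal sectors proportional to
# its area (largest-remainder rounding so counts sum exactly to R).
sphere_sectors <- function(theta, phi, R) {
  if (R == 1) return(rep(1L, length(theta)))
  nb <- max(1L, round(sqrt(R / 2)))
  edges <- acos(seq(1, -1, length.out = nb + 1))          # equal-area bands
  area <- diff(-cos(edges)) / 2
  raw <- area * R
  cnt <- floor(raw)
  rem <- R - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  cnt[cnt == 0] <- 1L
  while (sum(cnt) > R) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
  band <- findInterval(phi, edges, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1L), nb)
  offset <- cumsum(c(0L, cnt[-nb]))
  sector <- floor((theta + pi) / (2 * pi) * cnt[band])
  sector <- pmin(sector, cnt[band] - 1L)
  as.integer(offset[band] + sector + 1L)
}

#' Generate a clean two-contrast brain phantom with ground truth
#'
#' Builds piecewise-constant T1w and T2w volumes over a nested WM-core /
#' GM-ribbon / CSF / dura geometry, a tissue-label volume, and an ROI
#' parcellation of the ribbon into `n_roi` contiguous angular sectors.
#' The returned truth starts with unit bias fields, identity misalignment,
#' zero noise and an empty effect map; downstream generators fill these in.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel size in mm (length 3 or scalar).
#' @param geometry a [phantom_geometry()] list.
#' @param tissue_means a [phantom_tissue_means()] list.
#' @param n_roi number of ROI sectors over the ribbon (the parcellation
#'   stand-in; 82 mirrors a whole-cortex atlas).
#' @param seed integer; the clean phantom is deterministic, the seed is
#'   recorded for provenance of downstream draws.
#' @return list with `t1`, `t2` ([scalar_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
make_brain_phantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                               geometry = phantom_geometry(),
                               tissue_means = phantom_tissue_means(),
                               n_roi = 82, seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  g <- geometry
  if (g$gm_thickness < 2 * max(spacing))
    stop("invalid-geometry: ribbon thinner than 2 voxels at this spacing", call. = FALSE)
  if (any(unlist(tissue_means) < 0) ||
      any(tissue_means$t1[c("wm", "gm", "csf")] <= 0))
    stop("tissue means must be positive for brain tissues", call. = FALSE)
  if (tissue_means$t1[["wm"]] == tissue_means$t1[["gm"]] ||
      tissue_means$t1[["gm"]] == tissue_means$t1[["csf"]])
    stop("T1w tissue contrast must be nonzero", call. = FALSE)

  d <- as.integer(shape)
  ctr <- (d - 1) / 2 * spacing
  x <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)

  a <- g$wm_radii
  rho <- sqrt((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2)
  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- atan2(Y, X)
  phi <- acos(ifelse(r > 0, Z / r, 1))
  abar <- mean(a)
  pert <- 1 + g$perturb_amp * sin(g$perturb_freq * theta) * sin(2 * phi) *
    cos(g$perturb_freq * phi)

  t_wm <- pert
  t_gm <- pert * (1 + g$gm_thickness / abar)
  t_csf <- pert * (1 + (g$gm_thickness + g$csf_thickness) / abar)
  t_dura <- pert * (1 + (g$gm_thickness + g$csf_thickness + g$dura_thickness) / abar)

  region <- array(REGION[["background"]], d)
  region[rho < t_dura] <- REGION[["dura"]]
  region[rho < t_csf] <- REGION[["csf"]]
  region[rho < t_gm] <- REGION[["gm"]]
  region[rho < t_wm] <- REGION[["wm"]]

  gm <- region == REGION[["gm"]]
  if (!any(gm)) stop("invalid-geometry: no GM voxels", call. = FALSE)

  roi <- array(0L, d)
  roi[gm] <- sphere_sectors(theta[gm], phi[gm], as.integer(n_roi))

  lut1 <- c(tissue_means$t1[["background"]], tissue_means$t1[["gm"]],
            tissue_means$t1[["wm"]], tissue_means$t1[["dura"]],
            tissue_means$t1[["csf"]])
  lut2 <- c(tissue_means$t2[["background"]], tissue_means$t2[["gm"]],
            tissue_means$t2[["wm"]], tissue_means$t2[["dura"]],
            tissue_means$t2[["csf"]])
  t1 <- array(lut1[region + 1L], d)
  t2 <- array(lut2[region + 1L], d)

  tissue <- region
  tissue[tissue == REGION[["csf"]]] <- 0L  # public labels: background/CSF = 0

  unit <- array(1, d)
  truth <- structure(list(
    tissue_labels = tissue,
    region_labels = region,
    roi_labels = roi,
    head_mask = binary_mask(rho < t_dura, "head"),
    n_roi = as.integer(n_roi),
    spacing = spacing,
    receive_field = scalar_volume(unit, spacing),
    transmit_field_t1 = scalar_volume(unit, spacing),
    transmit_field_t2 = scalar_volume(unit, spacing),
    true_rigid = rigid_transform(center = ctr),
    effect_map = tibble::tibble(group = character(), roi_id = integer(),
                                delta = numeric()),
    noise_sigma = 0,
    tissue_means = tissue_means,
    geometry = g,
    seed = as.integer(seed)
  ), class = "phantom_truth")

  list(t1 = scalar_volume(t1, spacing),
       t2 = scalar_volume(t2, spacing),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s voxels, %d ROIs, %d GM voxels, noise sigma %.3g\n",
              paste(dim(x$tissue_labels), collapse = "x"), x$n_roi,
              sum(x$tissue_labels == 1L), x$noise_sigma))
  invisible(x)
}

#' Inject a group-dependent ratio effect into the clean T2w volume
#'
#' Within each ROI carrying a fractional ratio increase `delta` for `group`,
#' GM T2w intensities are divided by `(1 + delta)`, so the clean T1w/T2w
#' ratio rises by exactly that factor; all other voxels are untouched.
#' Scaling T2w down (rather than T1w up) is an arbitrary but fixed choice
#' that keeps the truth bookkeeping exact.
#'
#' @param t2_clean clean T2w [scalar_volume()].
#' @param truth a `phantom_truth` whose `effect_map` (tibble with columns
#'   `group`, `roi_id`, `delta`) defines the effects.
#' @param group character; group level to realize (absent levels mean no
#'   effect).
#' @return the modified T2w [scalar_volume()].
#' @export
apply_group_effect <- function(t2_clean, truth, group) {
  em <- truth$effect_map
  rows <- em[em$group == group, , drop = FALSE]
  if (nrow(rows) == 0) return(t2_clean)
  if (any(rows$delta <= -1))
    stop("invalid-effect: delta <= -1", call. = FALSE)
  out <- t2_clean$data
  gm <- truth$tissue_labels == 1L
  for (i in seq_len(nrow(rows))) {
    sel <- gm & truth$roi_labels == rows$roi_id[i]
    out[sel] <- out[sel] / (1 + rows$delta[i])
  }
  vol_like(t2_clean, out, allow_na = FALSE)
}

#' Draw smooth positive multiplicative bias fields
#'
#' Fields are exponentials of random low-order 3D polynomials in centred,
#' scaled coordinates: strictly positive, smooth, with log-amplitude
#' controlled by `strength`. One receive field (shared by both contrasts)
#' and two transmit fields (contrast-specific) emulate the B1-/B1+
#' distinction.
#'
#' @param shape grid dims; @param spacing mm; @param strength log-amplitude
#'   scale (0.15 gives roughly +/-25 percent fields); @param seed integer.
#' @return list of three [scalar_volume()]s: `receive`, `transmit_t1`,
#'   `transmit_t2`.
#' @export
draw_bias_fields <- function(shape, spacing = c(1, 1, 1), strength = 0.15,
                             seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- as.integer(shape)
  ctr <- (d - 1) / 2
  u <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) - ctr[a]) / max(ctr[a], 1))
  X <- array(rep(u[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(u[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(u[[3]], each = d[1] * d[2]), d)
  basis <- list(X, Y, Z, X * Y, X * Z, Y * Z, X^2, Y^2, Z^2)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  one_field <- function() {
    co <- rnorm(length(basis), 0, strength / sqrt(length(basis)))
    lf <- Reduce(`+`, Map(`*`, basis, as.list(co)))
    scalar_volume(exp(lf - mean(lf)), spacing)
  }
  list(receive = one_field(), transmit_t1 = one_field(), transmit_t2 = one_field())
}

#' Apply multiplicative bias fields and acquisition noise
#'
#' `t1_obs = t1 * receive * transmit_t1 + noise`, and likewise for T2w with
#' its own transmit field; the receive field is identical for both contrasts
#' (so it cancels in the ratio), and noise draws are independent between
#' contrasts. Noise sigma is `truth$noise_sigma` times the mean clean GM T1w
#' intensity, additive Gaussian by default with a Rician option (magnitude
#' of a complex Gaussian perturbation).
#'
#' @param t1,t2 clean [scalar_volume()]s.
#' @param truth `phantom_truth` carrying the bias fields and `noise_sigma`.
#' @param seed integer driving the noise draws.
#' @param noise `"gaussian"` or `"rician"`.
#' @return list `t1_obs`, `t2_obs`.
#' @export
apply_bias_and_noise <- function(t1, t2, truth, seed = 1L,
                                 noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  check_same_grid(t1, truth$receive_field, "volume and bias field")
  flds <- list(truth$receive_field, truth$transmit_field_t1, truth$transmit_field_t2)
  if (any(vapply(flds, function(f) any(f$data <= 0), logical(1))))
    stop("invalid-field: bias fields must be strictly positive", call. = FALSE)
  gm <- truth$tissue_labels == 1L
  sig <- truth$noise_sigma * mean(t1$data[gm])
  b1 <- t1$data * truth$receive_field$data * truth$transmit_field_t1$data
  b2 <- t2$data * truth$receive_field$data * truth$transmit_field_t2$data
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  n <- length(b1)
  if (sig > 0) {
    if (noise == "gaussian") {
      # clipped at zero: magnitude images are nonnegative
      b1 <- pmax(b1 + rnorm(n, 0, sig), 0)
      b2 <- pmax(b2 + rnorm(n, 0, sig), 0)
    } else {
      b1 <- sqrt((b1 + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2)
      b2 <- sqrt((b2 + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2)
    }
  }
  list(t1_obs = vol_like(t1, array(b1, dim(t1$data)), allow_na = FALSE),
       t2_obs = vol_like(t2, array(b2, dim(t2$data)), allow_na = FALSE))
}

#' Apply a small rigid misalignment to the observed T2w volume
#'
#' Resamples the volume under the rigid map with linear interpolation,
#' emulating the scanner-frame offset that intrasubject registration must
#' undo. Transforms are restricted to the phantom regime (|rotation| <= 15
#' degrees, |translation| <= 10 mm); a transform that moves an appreciable
#' part of the head out of the field of view is an error.
#'
#' @param t2_obs observed T2w [scalar_volume()].
#' @param rigid a [rigid_transform()].
#' @return the misaligned [scalar_volume()].
#' @export
apply_misalignment <- function(t2_obs, rigid) {
  if (any(abs(rigid$rotations) > 15) || any(abs(rigid$translations) > 10))
    stop("misalignment outside the phantom regime (<=15 deg, <=10 mm)", call. = FALSE)
  out <- resample(t2_obs, rigid, reference = t2_obs, interpolation = "linear")
  lost <- 1 - sum(out$data) / sum(t2_obs$data)
  if (is.finite(lost) && lost > 0.05)
    stop("out-of-fov: transform moves the head outside the field of view", call. = FALSE)
  out
}
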