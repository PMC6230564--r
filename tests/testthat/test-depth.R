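test_that("slab depth is linear and obeys the maximum principle", {
  d <- c(20, 20, 14)
  gm <- array(FALSE, d); gm[, , 5:10] <- TRUE
  wm <- array(FALSE, d); wm[, , 1:4] <- TRUE
  dm <- solve_laplace_depth(gm, wm, tol = 1e-7, max_iter = 20000)
  expect_true(dm$converged)
  prof <- apply(dm$depth[, , 5:10], 3, mean)
  expect_equal(prof, ((1:6) - 0.5) / 6, tolerance = 0.02)
  vals <- dm$depth[gm]
  expect_true(all(vals > 0 & vals < 1))
})

test_that("spherical-shell depth matches the closed-form harmonic solution", {
  sph <- sphere_shell_masks(64, a = 16, b = 26)
  dm <- solve_laplace_depth(sph$gm, sph$wm, tol = 1e-5, max_iter = 10000)
  a <- 16; b <- 26
  dt <- (1 / a - 1 / sph$r) / (1 / a - 1 / b)
  # coarser shell than the 96^3 reference run, so a looser staircase bound
  expect_lt(max(abs(dm$depth[sph$gm] - dt[sph$gm])), 0.05)
  expect_lt(mean(abs(dm$depth[sph$gm] - dt[sph$gm])), 0.01)
})

test_that("disconnected ribbon voxels raise a topology error or are dropped", {
  d <- c(16, 16, 16)
  gm <- array(FALSE, d); gm[, , 5:8] <- TRUE
  wm <- array(FALSE, d); wm[, , 1:4] <- TRUE
  gm[8, 8, 13] <- TRUE                      # island with no boundary path
  expect_error(solve_laplace_depth(gm, wm), "topology")
  dm <- solve_laplace_depth(gm, wm, on_topology = "drop")
  expect_equal(dm$dropped, 1L)
  expect_true(is.na(dm$depth[8, 8, 13]))
})

test_that("equivolume reparameterization: identity, sign, monotonicity", {
  sph <- sphere_shell_masks(48, a = 11, b = 19)
  dm <- solve_laplace_depth(sph$gm, sph$wm, tol = 1e-5, max_iter = 10000)
  # equal proxies: identity
  same <- equivolume_fraction(dm, 1, 1)
  expect_equal(same$depth[sph$gm], dm$depth[sph$gm], tolerance = 1e-12)
  # sphere: volume accumulates as r^3, so the half-volume surface sits
  # farther from the inner boundary than the equidistant midpoint
  # (closed form: r_half = ((a^3 + b^3)/2)^(1/3) = 15.96 > 15 for a=11, b=19)
  pr <- estimate_area_proxies(sph$gm, sph$wm)
  expect_gt(pr$outer, pr$inner)
  ev <- equivolume_fraction(dm, pr$inner, pr$outer)
  r_mid_eq <- mean(sph$r[sph$gm & abs(dm$depth - 0.5) < 0.05])
  r_mid_ev <- mean(sph$r[sph$gm & abs(ev$depth - 0.5) < 0.05])
  expect_gt(r_mid_ev, r_mid_eq + 0.4)   # moves toward r_half = 15.96
  # strictly increasing in original depth
  ord <- order(dm$depth[sph$gm])
  expect_true(all(diff(ev$depth[sph$gm][ord]) >= 0))
  # degenerate proxies fall back with a warning
  expect_warning(bad <- equivolume_fraction(dm, -1, 1), "degenerate")
  expect_equal(bad$depth, dm$depth)
  # slab: interface counts are equal and the correction vanishes
  d <- c(16, 16, 12)
  gm2 <- array(FALSE, d); gm2[, , 5:8] <- TRUE
  wm2 <- array(FALSE, d); wm2[, , 1:4] <- TRUE
  pr2 <- estimate_area_proxies(gm2, wm2)
  expect_equal(pr2$inner, pr2$outer)
})

test_that("mid-depth shell extraction restricts, bounds and inherits ROI ids", {
  ph <- small_phantom()
  gm <- ph$truth$tissue_labels == 1L
  wm <- ph$truth$region_labels == 2L
  dm <- solve_laplace_depth(gm, wm, spacing = ph$t1$spacing)
  # full band returns the whole ribbon
  full <- extract_middepth_shell(dm, 0.5, ph$truth$roi_labels)
  expect_equal(sum(full$mask), sum(gm))
  shell <- extract_middepth_shell(dm, 0.1, ph$truth$roi_labels)
  expect_true(all(shell$mask[shell$mask] & gm[shell$mask]))  # subset of GM
  expect_false(any(shell$mask & wm))
  expect_false(any(shell$mask & ph$truth$region_labels == 4L))
  idx <- which(shell$mask)
  expect_identical(shell$roi[idx], ph$truth$roi_labels[idx])  # no relabeling
  expect_true(all(shell$roi[idx] >= 1L))
  expect_error(extract_middepth_shell(dm, 1e-9, ph$truth$roi_labels),
               "band-too-narrow")
})

test_that("a 3 mm slab ribbon yields a one-voxel mid sheet at w = 0.1", {
  d <- c(16, 16, 11)
  gm <- array(FALSE, d); gm[, , 5:7] <- TRUE   # 3-voxel ribbon
  wm <- array(FALSE, d); wm[, , 1:4] <- TRUE
  dm <- solve_laplace_depth(gm, wm, tol = 1e-7, max_iter = 20000)
  roi <- array(0L, d); roi[gm] <- 1L
  shell <- extract_middepth_shell(dm, 0.1, roi)
  expect_true(all(which(shell$mask, arr.ind = TRUE)[, 3] == 6))
  expect_equal(sum(shell$mask), 16 * 16)
})

test_that("on-shell smoothing preserves constants, mass and locality", {
  ph <- small_phantom()
  gm <- ph$truth$tissue_labels == 1L
  wm <- ph$truth$region_labels == 2L
  dm <- solve_laplace_depth(gm, wm, spacing = ph$t1$spacing)
  shell <- extract_middepth_shell(dm, 0.1, ph$truth$roi_labels)
  # constant field unchanged on the curved shell
  cst <- array(2.5, dim(gm))
  sm <- smooth_on_shell(cst, shell, fwhm = 6)
  expect_equal(sm[shell$mask], rep(2.5, sum(shell$mask)), tolerance = 1e-9)
  idx <- which(shell$mask, arr.ind = TRUE)
  ctr <- idx[which.min(rowSums(sweep(idx, 2, colMeans(idx))^2)), ]
  spike <- array(0, dim(gm)); spike[ctr[1], ctr[2], ctr[3]] <- 1
  sm2 <- smooth_on_shell(spike, shell, fwhm = 6)
  expect_lt(sm2[ctr[1], ctr[2], ctr[3]], 1)
  # linearity and positivity
  sm3 <- smooth_on_shell(2 * spike + cst, shell, fwhm = 6)
  expect_equal(sm3[shell$mask], 2 * sm2[shell$mask] + sm[shell$mask],
               tolerance = 1e-9)
  expect_true(all(sm2[shell$mask] >= 0))
  # NA voxels are carried as missing and do not contaminate neighbours
  v <- cst; v[ctr[1], ctr[2], ctr[3]] <- NA
  sm4 <- smooth_on_shell(v, shell, fwhm = 6)
  expect_true(is.na(sm4[ctr[1], ctr[2], ctr[3]]))
  expect_equal(sm4[shell$mask & !is.na(v)],
               rep(2.5, sum(shell$mask) - 1), tolerance = 1e-9)
})

test_that("a spike's in-shell mass is conserved on a translation-invariant shell", {
  # the renormalized kernel sums to one wherever the shell looks the same
  # from every voxel, i.e. on a flat sheet away from its rim
  d <- c(48, 48, 9)
  gm <- array(FALSE, d); gm[, , 4:6] <- TRUE
  wm <- array(FALSE, d); wm[, , 1:3] <- TRUE
  dmf <- solve_laplace_depth(gm, wm, tol = 1e-7, max_iter = 20000)
  roi <- array(0L, d); roi[gm] <- 1L
  sh <- extract_middepth_shell(dmf, 0.1, roi)
  spike <- array(0, d); spike[24, 24, 5] <- 1
  smf <- smooth_on_shell(spike, sh, fwhm = 6)
  expect_lt(smf[24, 24, 5], 1)
  expect_equal(sum(smf[sh$mask]), 1, tolerance = 1e-6)
})

test_that("step-edge transition width on a slab shell is consistent with the kernel", {
  d <- c(60, 24, 9)
  gm <- array(FALSE, d); gm[, , 4:6] <- TRUE
  wm <- array(FALSE, d); wm[, , 1:3] <- TRUE
  dm <- solve_laplace_depth(gm, wm, tol = 1e-7, max_iter = 20000)
  roi <- array(0L, d); roi[gm] <- ifelse(which(array(TRUE, d), arr.ind = TRUE)[gm, 1] <= 30, 1L, 2L)
  shell <- extract_middepth_shell(dm, 0.2, roi)
  step <- array(0, d); step[, , 5][31:60, ] <- 1
  sm <- smooth_on_shell(step, shell, fwhm = 6)
  prof <- vapply(1:60, function(i) mean(sm[i, , 5]), numeric(1))
  x10 <- approx(prof, 1:60, xout = 0.1, ties = mean)$y
  x90 <- approx(prof, 1:60, xout = 0.9, ties = mean)$y
  width <- abs(x90 - x10)
  # 10-90% width of a Gaussian-blurred step = 2.563 sigma; fwhm 6 -> 6.53 mm
  expect_lt(abs(width - 6.53), 0.2 * 6.53)
})
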