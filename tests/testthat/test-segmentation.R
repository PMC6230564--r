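test_that("local intensity normalization handles constants, bias and spikes", {
  # constant image normalizes to exactly 1
  v <- scalar_volume(array(3.7, c(24, 24, 24)))
  out <- local_intensity_normalize(v)
  expect_equal(out$data, array(1, c(24, 24, 24)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # slow multiplicative bias: within-tissue CoV shrinks at least 2x
  d <- c(48, 48, 48)
  co <- which(array(TRUE, d), arr.ind = TRUE)
  bias <- exp(0.6 * (co[, 1] - 24) / 48 + 0.5 * (co[, 2] - 24) / 48)
  tissue <- array(1, d)
  tissue[co[, 3] > 24] <- 0.7          # two flat tissue slabs
  img <- scalar_volume(array(tissue * bias, d))
  norm <- local_intensity_normalize(img)
  m1 <- array(co[, 3] <= 24, d)
  expect_lt(cov_within(norm$data, m1), cov_within(img$data, m1) / 2)
  expect_lt(cov_within(norm$data, !m1), cov_within(img$data, !m1) / 2)

  # an isolated bright voxel yields a finite, flagged-free normalization
  # (the smoothed envelope necessarily dilutes an isolated peak, so the
  # value exceeds 1 there; what matters is that it stays finite and the
  # empty surround is floor-guarded)
  z <- array(0, c(24, 24, 24)); z[12, 12, 12] <- 5
  nz <- local_intensity_normalize(scalar_volume(z))
  expect_true(is.finite(nz$data[12, 12, 12]))
  expect_true(any(attr(nz, "floored")))

  expect_error(local_intensity_normalize(scalar_volume(array(0, c(8, 8, 8)))),
               "degenerate-input")
  expect_error(local_intensity_normalize(v, window = 4L), "odd")
})

test_that("CSF threshold lands between modes and falls back when unimodal", {
  set.seed(2)
  x <- c(rnorm(5000, 0.2, 0.015), rnorm(5000, 0.7, 0.015))
  est <- estimate_csf_threshold(x)
  expect_equal(est$method, "valley")
  expect_gt(est$threshold, 0.25)
  expect_lt(est$threshold, 0.65)
  expect_warning(est1 <- estimate_csf_threshold(rnorm(3000, 0.5, 0.05)),
                 "unimodal")
  expect_equal(est1$method, "otsu")
  expect_error(estimate_csf_threshold(runif(100)), "1000")
})

test_that("noiseless phantom thresholding reproduces the non-CSF mask", {
  ph <- small_phantom()
  norm <- local_intensity_normalize(ph$t1, mask = ph$truth$head_mask)
  est <- estimate_csf_threshold(norm$data[ph$truth$head_mask])
  reg <- ph$truth$region_labels
  non_csf <- ph$truth$head_mask & reg != 4L
  got <- ph$truth$head_mask & norm$data > est$threshold
  expect_equal(got, array(non_csf, dim(got)), ignore_attr = TRUE)
})

test_that("skull strip removes dura, keeps the cerebrum, and opening is stable", {
  ph <- small_phantom()
  norm <- local_intensity_normalize(ph$t1, mask = ph$truth$head_mask)
  cer <- skull_strip(norm, ph$truth$head_mask)
  reg <- ph$truth$region_labels
  expect_equal(sum(cer & reg == 3L), 0)                     # zero dura voxels
  truth_cer <- reg %in% c(1L, 2L)
  expect_gte(sum(cer & truth_cer) / sum(truth_cer), 0.99)   # >=99% of GM+WM
  # erode-then-dilate is the identity on a convex set that is a ball of the
  # element's own (city-block) metric and larger than the element
  d24 <- c(24, 24, 24)
  co <- which(array(TRUE, d24), arr.ind = TRUE)
  octa <- array(rowSums(abs(sweep(co, 2, c(12, 12, 12)))) <= 7, d24)
  opened <- cortexratio:::dilate6(cortexratio:::erode6(octa))
  expect_identical(opened, octa)
})

test_that("upsample/downsample round trip conserves smooth mask volume", {
  ph <- small_phantom()
  m <- array(ph$truth$region_labels %in% c(1L, 2L),
             dim(ph$truth$region_labels))
  v <- array(as.numeric(m), dim(m))
  A <- cbind(diag(0.5, 3), c(0, 0, 0))
  up <- cortexratio:::cpp_resample_affine(v, as.integer(2L * dim(v)), A, 0L)$values
  dn <- cortexratio:::cpp_block_mean(up, 2L) >= 0.5
  expect_lt(abs(sum(dn) - sum(m)) / sum(m), 0.01)
})

test_that("fuzzy c-means hits the exact fixed point on two-valued data", {
  z <- array(rep(c(0.3, 0.9), each = 500), c(10, 10, 10))
  v <- scalar_volume(z)
  seg <- fuzzy_segment(v, array(TRUE, dim(z)), spatial_beta = 0)
  expect_equal(sort(seg$centroids), c(0.3, 0.9), tolerance = 1e-9)
  mem1 <- seg$memberships[[1]]
  expect_true(all(abs(mem1[z == 0.3] - 1) < 1e-9))
  expect_true(all(mem1[z == 0.9] < 1e-9))
  # objective trace is non-increasing for plain FCM
  expect_true(all(diff(seg$objective) <= 1e-12))
  expect_error(fuzzy_segment(scalar_volume(array(1, c(8, 8, 8))),
                             array(TRUE, c(8, 8, 8))), "degenerate-input")
})

test_that("memberships sum to one and match brute-force two-means on separable data", {
  set.seed(5)
  z <- array(c(rnorm(300, 0.3, 0.02), rnorm(200, 0.85, 0.02)), c(10, 10, 5))
  v <- scalar_volume(z)
  mask <- array(TRUE, dim(z))
  seg <- fuzzy_segment(v, mask, spatial_beta = 0)
  tot <- seg$memberships[[1]] + seg$memberships[[2]]
  expect_true(all(abs(tot[mask] - 1) < 1e-9))
  oracle <- two_means_brute(as.vector(z))
  expect_identical(as.vector(seg$hard_labels), oracle$labels)
})

test_that("spatial regularization improves noisy segmentation", {
  # at mild noise the residual errors are geometric (partial volume at the
  # mask edge) and the penalty is inert; 5% noise exercises the mechanism
  ph <- small_phantom()
  tr <- ph$truth; tr$noise_sigma <- 0.05
  obs <- apply_bias_and_noise(ph$t1, ph$t2, tr, seed = 7)
  norm <- local_intensity_normalize(obs$t1_obs, mask = ph$truth$head_mask)
  cer <- skull_strip(norm, ph$truth$head_mask)
  gm <- ph$truth$tissue_labels == 1L
  wm <- ph$truth$region_labels == 2L
  s0 <- fuzzy_segment(norm, cer, spatial_beta = 0)
  s1 <- fuzzy_segment(norm, cer, spatial_beta = 0.02)
  d0 <- dice(s0$hard_labels == 1L, gm) + dice(s0$hard_labels == 2L, wm)
  d1 <- dice(s1$hard_labels == 1L, gm) + dice(s1$hard_labels == 2L, wm)
  expect_gt(d1, d0)
})
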