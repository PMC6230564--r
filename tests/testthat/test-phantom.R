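test_that("ROI labels partition the ribbon and tissues are correctly ordered", {
  ph <- make_brain_phantom(shape = c(64, 64, 64), n_roi = 8, seed = 1)
  gm <- ph$truth$tissue_labels == 1L
  expect_true(all(ph$truth$roi_labels[gm] %in% 1:8))
  expect_true(all(ph$truth$roi_labels[!gm] == 0L))
  expect_setequal(unique(ph$truth$roi_labels[gm]), 1:8)
  # clean ratio ordering forced by the tissue means: WM > GM > CSF
  reg <- ph$truth$region_labels
  ratio <- ph$t1$data / pmax(ph$t2$data, 1e-9)
  expect_gt(min(ratio[reg == 2L]), max(ratio[reg == 1L]))
  expect_gt(min(ratio[reg == 1L]), max(ratio[reg == 4L]))
})

test_that("phantom generation is deterministic and validates geometry", {
  a <- make_brain_phantom(shape = c(32, 32, 32), seed = 9)
  b <- make_brain_phantom(shape = c(32, 32, 32), seed = 9)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$t2$data, b$t2$data)
  expect_identical(a$truth$roi_labels, b$truth$roi_labels)
  expect_error(make_brain_phantom(spacing = c(4, 4, 4)), "invalid-geometry")
})

test_that("tissue labels are topologically nested", {
  ph <- small_phantom()
  lab <- ph$truth$tissue_labels
  gm <- lab == 1L; wm <- lab == 2L; dura <- lab == 3L
  bg_far <- lab == 0L & !ph$truth$head_mask              # true background
  csf <- ph$truth$region_labels == 4L
  # WM is interior to the GM shell: it only touches WM or GM
  expect_false(cortexratio:::touches26(wm, lab == 0L))
  expect_false(cortexratio:::touches26(wm, dura))
  # GM never reaches open background without passing CSF or dura
  expect_false(cortexratio:::touches26(gm, bg_far))
  expect_true(cortexratio:::touches26(gm, csf))
})

test_that("group effects scale the clean ratio exactly and locally", {
  ph <- small_phantom()
  truth <- ph$truth
  truth$effect_map <- tibble::tibble(group = c("HD2", "HD2"),
                                     roi_id = c(3L, 7L), delta = 0.05)
  # null effect: control untouched
  expect_identical(apply_group_effect(ph$t2, truth, "Control")$data, ph$t2$data)
  out <- apply_group_effect(ph$t2, truth, "HD2")
  gm <- truth$tissue_labels == 1L
  hit <- gm & truth$roi_labels %in% c(3L, 7L)
  r0 <- ph$t1$data / ph$t2$data
  r1 <- ph$t1$data / out$data
  expect_equal(r1[hit], 1.05 * r0[hit], tolerance = 1e-12)
  expect_identical(r1[!hit], r0[!hit])
  truth$effect_map$delta <- c(-1, 0.05)
  expect_error(apply_group_effect(ph$t2, truth, "HD2"), "invalid-effect")
})

test_that("bias application is multiplicative, shared-receive and reproducible", {
  ph <- small_phantom()
  truth <- ph$truth
  # unit fields, zero noise: identity
  obs <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 1)
  expect_identical(obs$t1_obs$data, ph$t1$data)
  expect_identical(obs$t2_obs$data, ph$t2$data)
  # shared receive field cancels voxelwise in the ratio
  flds <- draw_bias_fields(dim(ph$t1$data), ph$t1$spacing, 0.3, seed = 2)
  truth$receive_field <- flds$receive
  obs <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 1)
  inside <- ph$t2$data > 0
  expect_equal(obs$t1_obs$data[inside] / obs$t2_obs$data[inside],
               ph$t1$data[inside] / ph$t2$data[inside], tolerance = 1e-10)
  # fixed seed reproduces the noise realization; different seed does not
  truth$noise_sigma <- 0.05
  n1 <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 7)
  n2 <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 7)
  n3 <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 8)
  expect_identical(n1$t1_obs$data, n2$t1_obs$data)
  expect_false(identical(n1$t1_obs$data, n3$t1_obs$data))
  # rician option stays nonnegative
  nr <- apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 7, noise = "rician")
  expect_true(all(nr$t1_obs$data >= 0))
  # nonpositive field rejected
  truth$receive_field$data[1] <- 0
  expect_error(apply_bias_and_noise(ph$t1, ph$t2, truth, seed = 1),
               "invalid-field")
})

test_that("misalignment respects the phantom regime and the fov", {
  ph <- small_phantom()
  expect_error(apply_misalignment(ph$t2, rigid_transform(c(20, 0, 0))),
               "phantom regime")
  out <- apply_misalignment(ph$t2, rigid_transform())
  expect_equal(out$data, ph$t2$data, tolerance = 1e-12, ignore_attr = TRUE)
  # a head filling a tight fov cannot be translated 8 mm without leaving it
  tight <- make_brain_phantom(shape = c(40, 40, 40),
                              geometry = phantom_geometry(
                                wm_radii = c(10.5, 9.75, 9.4),
                                gm_thickness = 4, csf_thickness = 2,
                                dura_thickness = 1),
                              seed = 2)
  expect_error(apply_misalignment(tight$t2,
                                  rigid_transform(translations = c(8, 8, 8))),
               "out-of-fov")
})

test_that("simulate_cohort counts files, rows and is seed-deterministic", {
  counts <- matrix(3L, 5, 2,
                   dimnames = list(c("Control", "PreHD-A", "PreHD-B", "HD1", "HD2"),
                                   c("site1", "site2")))
  spec <- cohort_spec(counts = counts, shape = c(32, 32, 32),
                      geometry = phantom_geometry(wm_radii = c(7, 6.6, 6.3),
                                                  gm_thickness = 3,
                                                  csf_thickness = 2,
                                                  dura_thickness = 1),
                      seed = 5)
  dir1 <- file.path(tempdir(), "coh1")
  coh <- simulate_cohort(spec, out_dir = dir1, keep_volumes = TRUE)
  expect_equal(nrow(coh$manifest), 30L)
  expect_length(list.files(dir1, pattern = "_t[12]w\\.nii\\.gz$"), 60L)
  # determinism: identical manifests and voxel data
  coh2 <- simulate_cohort(spec)
  expect_equal(coh$manifest[c("subject_id", "group", "age", "site", "seed")],
               coh2$manifest[c("subject_id", "group", "age", "site", "seed")])
  expect_identical(coh$subjects[[7]]$t1$data, coh2$subjects[[7]]$t1$data)
  expect_identical(coh$subjects[[7]]$t2$data, coh2$subjects[[7]]$t2$data)
  # spec YAML round trip preserves the realization
  spec2 <- read_cohort_spec(file.path(dir1, "cohort_spec.yaml"))
  coh3 <- simulate_cohort(spec2)
  expect_identical(coh$subjects[[3]]$t1$data, coh3$subjects[[3]]$t1$data)
  unlink(dir1, recursive = TRUE)
  # every site needs a control
  bad <- counts; bad["Control", 1] <- 0L
  expect_error(cohort_spec(counts = bad, seed = 1), "Control")
})
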