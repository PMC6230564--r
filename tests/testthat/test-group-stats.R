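test_that("QC exclusion implements the 1.5-SD gain-difference rule", {
  subj <- tibble::tibble(subject_id = letters[1:5],
                         mean_signal = c(1, 1, 1, 1, 3))
  out <- qc_exclude(subj, k = 1.5)
  # mean 1.4, sd 0.8944: only |3 - 1.4| = 1.6 > 1.3416 is flagged
  expect_identical(out$qc_excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(out$qc_reason[5], "gain difference")
  # all-equal cohort: zero SD, warning, nothing flagged
  expect_warning(eq <- qc_exclude(tibble::tibble(subject_id = 1:4,
                                                 mean_signal = rep(2, 4))),
                 "zero cohort SD")
  expect_false(any(eq$qc_excluded))
  # infinite k excludes nobody
  expect_false(any(qc_exclude(subj, k = Inf)$qc_excluded))
  expect_error(qc_exclude(subj[1:2, ]), "3 subjects")
})

test_that("ROI table aggregation: means, sample SD, counting, missing rows", {
  long <- tibble::tibble(subject_id = rep(c("a", "b"), c(3, 2)),
                         roi_id = c(1L, 1L, 2L, 1L, 1L),
                         value = c(1, 3, 5, 2, NA))
  tab <- build_roi_table(long, n_roi = 2)
  expect_equal(nrow(tab), 4L)                       # 2 subjects x 2 ROIs
  a1 <- tab[tab$subject_id == "a" & tab$roi_id == 1L, ]
  expect_equal(a1$mean_signal, 2)
  expect_equal(a1$sd_signal, sqrt(2), tolerance = 1e-12)  # sample SD of {1,3}
  expect_equal(a1$n_voxels, 2L)
  b2 <- tab[tab$subject_id == "b" & tab$roi_id == 2L, ]
  expect_true(is.na(b2$mean_signal))                # absent ROI gets NA row
  expect_equal(b2$n_voxels, 0L)
  # constant ROI: SD exactly zero
  cst <- build_roi_table(tibble::tibble(subject_id = "a", roi_id = 1L,
                                        value = rep(4.2, 6)))
  expect_equal(cst$mean_signal, 4.2)
  expect_equal(cst$sd_signal, 0)
})

test_that("Holm-Bonferroni matches the hand-computed stepdown example", {
  out <- holm_bonferroni(c(0.001, 0.02, 0.04), m = 3, alpha = 0.05)
  expect_equal(out$p_adjusted, c(0.003, 0.04, 0.04))
  expect_true(all(out$significant))
  # m = 1 is the identity
  one <- holm_bonferroni(0.031, m = 1)
  expect_equal(one$p_adjusted, 0.031)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "invalid-input")
  expect_error(holm_bonferroni(c(0.5, 0.1), m = 1), "family size")
})

test_that("Holm equals brute-force stepdown on 1000 random p-vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:82, 1)
    m <- n + sample(0:(82 - n), 1)
    p <- round(runif(n)^sample(1:3, 1), 6)
    got <- holm_bonferroni(p, m = m, alpha = 0.05)
    want <- holm_brute(p, m = m, alpha = 0.05)
    if (!isTRUE(all.equal(got$p_adjusted, want$adjusted, tolerance = 1e-12)) ||
        !identical(got$significant, want$significant)) {
      fail(sprintf("mismatch at i=%d (n=%d, m=%d)", i, n, m))
    }
  }
  succeed()
  # adjusted sequence is monotone non-decreasing in raw-p order
  p <- runif(50)
  adj <- holm_bonferroni(p, m = 82)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= 0))
  # significance <=> adjusted p below alpha
  out <- holm_bonferroni(runif(40)^2, m = 60, alpha = 0.05)
  expect_identical(out$significant, out$p_adjusted < 0.05)
})

test_that("WLS with equal weights reduces to OLS", {
  subj <- synth_subjects(n_per_group = 5)
  tab <- synth_roi_table(subj, n_roi = 4, noise_sd = 0.01, seed = 3)
  tab$sd_signal <- 0.02                      # equal weights everywhere
  fit <- fit_roi_wls(tab, subj, weight_scheme = "per_subject")
  d <- dplyr::inner_join(tab[tab$roi_id == 2L, ],
                         subj[c("subject_id", "group", "age", "site")],
                         by = "subject_id")
  d$group <- factor(d$group, levels = unique(subj$group))
  ols <- lm(mean_signal ~ age + site + group, data = d)
  got <- fit$results[fit$results$roi_id == 2L, ]
  expect_equal(got$estimate, unname(coef(ols)["groupHD1"]), tolerance = 1e-10)
  expect_equal(got$p_value,
               unname(summary(ols)$coefficients["groupHD1", 4]),
               tolerance = 1e-10)
})

test_that("noiseless synthetic tables are recovered exactly", {
  subj <- synth_subjects(n_per_group = 4,
                         groups = c("Control", "PreHD-A", "HD1"))
  tab <- synth_roi_table(subj, n_roi = 6, b_age = -0.001,
                         group_offsets = c(Control = 0, `PreHD-A` = 0.01,
                                           HD1 = 0.05),
                         noise_sd = 0)
  fit <- suppressWarnings(fit_roi_wls(tab, subj))  # exact fit: SEs are zero
  hd1 <- fit$results[fit$results$term == "HD1", ]
  expect_true(all(abs(hd1$estimate - 0.05) < 1e-8))
  age <- fit$covariate_terms[fit$covariate_terms$term == "age", ]
  expect_true(all(abs(age$estimate + 0.001) < 1e-8))
})

test_that("WLS coverage: estimates within 2 SE of truth in >=95% of replicates", {
  subj <- synth_subjects(n_per_group = 50, groups = c("Control", "HD1"),
                         seed = 11)  # 200 subjects over 2 sites
  hits <- 0L
  for (r in 1:100) {
    tab <- synth_roi_table(subj, n_roi = 1, group_offsets = c(Control = 0, HD1 = 0.05),
                           noise_sd = 0.02, seed = 1000 + r)
    fit <- fit_roi_wls(tab, subj)
    row <- fit$results[fit$results$term == "HD1", ]
    if (abs(row$estimate - 0.05) <= 2 * row$std_error) hits <- hits + 1L
  }
  expect_gte(hits, 90)   # binomial tolerance around the nominal 95 of 100
})

test_that("vertexwise maps: null covariates, treatment coding, injected effect", {
  set.seed(21)
  subj <- synth_subjects(n_per_group = 8, groups = c("Control", "HD1"))
  nv <- 40
  base <- 0.9
  eff <- c(rep(0.05, 10), rep(0, 30))
  Y <- matrix(base, nrow(subj), nv)
  Y <- Y + outer(as.integer(subj$group == "HD1"), eff)
  Y <- Y + matrix(rnorm(length(Y), 0, 1e-3), nrow(subj))
  vm <- vertexwise_group_maps(Y, subj)
  expect_equal(unname(vm$coefficients["Control", ]), rep(0, nv))
  expect_equal(unname(vm$coefficients["HD1", 1:10]), rep(0.05, 10),
               tolerance = 0.01)
  expect_equal(unname(vm$coefficients["HD1", 11:40]), rep(0, 30),
               tolerance = 0.01)
  # with zero age/site effects the adjusted map equals the raw group mean
  expect_equal(unname(vm$group_means["HD1", ]),
               unname(colMeans(Y[subj$group == "HD1", ])), tolerance = 2e-3)
})
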