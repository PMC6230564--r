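# Shared fixtures and independent oracles, built in code at test time.

# Small phantom (48^3, cohort-scale head), cached per session (deterministic).
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_brain_phantom(
        shape = c(48, 48, 48),
        geometry = phantom_geometry(wm_radii = c(10.5, 9.75, 9.4),
                                    gm_thickness = 4, csf_thickness = 2,
                                    dura_thickness = 1),
        seed = 1)
    cache
  }
})

# Spherical-shell masks on an n^3 grid: WM core r < a, ribbon a <= r < b.
sphere_shell_masks <- function(n, a, b) {
  d <- c(n, n, n)
  ctr <- (d - 1) / 2
  co <- which(array(TRUE, d), arr.ind = TRUE)
  r <- array(sqrt(rowSums(sweep(co, 2, ctr)^2)), d)
  list(r = r, wm = r < a, gm = r >= a & r < b)
}

# Independent brute-force Holm stepdown (sort, scan, cummax), kept free of
# stats::p.adjust so it can serve as the oracle for the packaged operation.
holm_brute <- function(p, m = length(p), alpha = 0.05) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- max(cur, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- cur
  }
  sig <- logical(n)
  for (i in seq_len(n)) {
    if (p[ord[i]] < alpha / (m - i + 1)) sig[ord[i]] <- TRUE else break
  }
  list(adjusted = adj, significant = sig)
}

# Exhaustive two-means split of a 1D sample: every threshold between sorted
# values, minimizing within-class sum of squares.
two_means_brute <- function(x) {
  xs <- sort(unique(x))
  best <- NULL
  best_sse <- Inf
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    lo <- x[x <= thr]; hi <- x[x > thr]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best_sse) { best_sse <- sse; best <- thr }
  }
  list(threshold = best, labels = as.integer(x > best) + 1L, sse = best_sse)
}

# Coefficient of variation within a tissue mask.
cov_within <- function(values, mask) {
  v <- values[mask]
  sd(v) / mean(v)
}

# Build a synthetic ROI signal table from known regression coefficients
# (exact, noiseless unless sd > 0): signal = base + b_age*age + site and
# group offsets.
synth_roi_table <- function(subjects, n_roi, base = 0.9, b_age = -0.001,
                            site_offsets = c(site1 = 0, site2 = 0.01),
                            group_offsets = c(Control = 0),
                            affected = integer(0), delta = 0,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    g_off <- if (s$group %in% names(group_offsets)) group_offsets[[s$group]] else 0
    mu <- base + b_age * s$age + site_offsets[[s$site]] + g_off
    mu_roi <- rep(mu, n_roi)
    if (s$group %in% c("HD1", "HD2") && length(affected))
      mu_roi[affected] <- mu_roi[affected] + delta
    tibble::tibble(subject_id = s$subject_id, roi_id = seq_len(n_roi),
                   mean_signal = mu_roi + rnorm(n_roi, 0, noise_sd),
                   sd_signal = 0.01, n_voxels = 10L)
  })
  dplyr::bind_rows(rows)
}

synth_subjects <- function(n_per_group = 4,
                           groups = c("Control", "HD1"),
                           sites = c("site1", "site2"), seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(group = groups, site = sites,
                             k = seq_len(n_per_group))
  tibble::tibble(subject_id = sprintf("T%03d", seq_len(nrow(grid))),
                 group = grid$group, site = grid$site,
                 age = round(runif(nrow(grid), 30, 60), 1))
}
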