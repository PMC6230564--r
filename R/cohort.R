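#' Default HD-style effect map
#'
#' A fractional ratio increase `delta` in `n_affected` ROIs spread over the
#' parcellation, injected for the listed (typically manifest-disease) groups.
#' The magnitude of the real-data effect is not published numerically, so the
#' default is a free parameter of the simulation, not a literature value.
#'
#' @param n_roi total number of ROIs in the parcellation.
#' @param groups group levels receiving the effect.
#' @param delta fractional ratio increase (0.05 = 5 percent).
#' @param roi_ids which ROIs are affected; default spreads `n_affected`
#'   evenly across the parcellation.
#' @param n_affected number of affected ROIs when `roi_ids` is `NULL`.
#' @return tibble with columns `group`, `roi_id`, `delta`.
#' @export
hd_effect_map <- function(n_roi = 82, groups = c("HD1", "HD2"), delta = 0.05,
                          roi_ids = NULL, n_affected = 6) {
  if (is.null(roi_ids))
    roi_ids <- unique(pmax(1L, round(seq(0.12, 0.88, length.out = n_affected) * n_roi)))
  tidyr::expand_grid(group = groups, roi_id = as.integer(roi_ids)) |>
    dplyr::mutate(delta = delta)
}

#' Specification of a synthetic multi-site cohort
#'
#' Declares the study conditions a simulated cohort realizes: group sizes
#' per site, per-group age distributions, per-site scanner differences
#' (intensity scales and bias-field draws), the injected disease effect, the
#' noise model, rigid T2w misalignment, and the master seed. Age means and
#' SDs default to the demographics of a five-group HD staging cohort
#' (healthy controls, two premanifest strata, two early-disease stages).
#'
#' @param groups factor levels, first level is the reference (Control).
#' @param sites site labels (at least 2 for a multi-site design).
#' @param counts matrix of subjects per group (rows) and site (columns);
#'   every site needs at least one Control.
#' @param age_params tibble with `group`, `mean`, `sd` (years).
#' @param age_slope linear age effect on the clean GM ratio, per year
#'   (small negative by default, as ratio signal drifts with age).
#' @param ref_age age at which the age effect is zero.
#' @param site_scale_sdlog lognormal sd of per-site global intensity scales,
#'   drawn independently per contrast.
#' @param bias_strength log-amplitude of per-site bias-field draws
#'   (see [draw_bias_fields()]).
#' @param effect_map tibble `(group, roi_id, delta)`; see [hd_effect_map()].
#' @param noise list `type` (`"gaussian"` or `"rician"`) and `sigma`
#'   (fraction of mean GM T1w intensity).
#' @param misalign list `rot_sd` (deg) and `trans_sd` (mm) of the random
#'   rigid T2w offset (truncated at 3 sd).
#' @param shape,spacing,geometry,tissue_means,n_roi phantom parameters
#'   (see [make_brain_phantom()]).
#' @param seed master seed; recorded in the output manifest.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("Control", "PreHD-A", "PreHD-B", "HD1", "HD2"),
                        sites = c("site1", "site2"),
                        counts = NULL,
                        age_params = NULL,
                        age_slope = -0.001, ref_age = 45,
                        site_scale_sdlog = 0.05,
                        bias_strength = 0.15,
                        effect_map = NULL,
                        noise = list(type = "gaussian", sigma = 0.02),
                        misalign = list(rot_sd = 1, trans_sd = 1),
                        shape = c(48, 48, 48), spacing = c(1, 1, 1),
                        geometry = NULL, tissue_means = phantom_tissue_means(),
                        n_roi = 82, seed = 1L) {
  if (is.null(counts)) {
    # Table-1-like proportions (112:54:51:68:41) scaled to ~6 per group/site
    per <- c(Control = 10, `PreHD-A` = 5, `PreHD-B` = 5, HD1 = 6, HD2 = 4)
    per <- per[groups]
    per[is.na(per)] <- 5
    counts <- matrix(rep(ceiling(per / length(sites)), length(sites)),
                     nrow = length(groups), dimnames = list(groups, sites))
  }
  if (is.null(age_params)) {
    defaults <- tibble::tibble(
      group = c("Control", "PreHD-A", "PreHD-B", "HD1", "HD2"),
      mean = c(46.1, 40.6, 39.6, 47.1, 50.9),
      sd = c(10.5, 8.7, 8.8, 10.2, 8.8))
    age_params <- dplyr::left_join(tibble::tibble(group = groups), defaults,
                                   by = "group")
    age_params$mean[is.na(age_params$mean)] <- 45
    age_params$sd[is.na(age_params$sd)] <- 10
  }
  if (is.null(effect_map)) effect_map <- hd_effect_map(n_roi)
  if (is.null(geometry)) {
    # head radii scale with the fov; cortical ribbon, CSF gap and dura keep
    # their physical thickness (cortex does not scale with head size)
    sc <- min(shape * spacing) / 64
    geometry <- phantom_geometry(wm_radii = c(14, 13, 12.5) * sc,
                                 gm_thickness = max(4, 2.5 * max(spacing)),
                                 csf_thickness = max(2, 2 * max(spacing)),
                                 dura_thickness = min(1, max(spacing)))
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- groups
  if (is.null(colnames(counts))) colnames(counts) <- sites
  if (any(counts[groups[1], ] < 1))
    stop("every site needs at least one ", groups[1], " subject", call. = FALSE)
  if (any(effect_map$delta < -1))
    stop("effect_map deltas must be >= -1", call. = FALSE)
  structure(list(groups = groups, sites = sites, counts = counts,
                 age_params = age_params, age_slope = age_slope,
                 ref_age = ref_age, site_scale_sdlog = site_scale_sdlog,
                 bias_strength = bias_strength, effect_map = effect_map,
                 noise = noise, misalign = misalign, shape = shape,
                 spacing = spacing, geometry = geometry,
                 tissue_means = tissue_means, n_roi = n_roi,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects: %d groups x %d sites, %s grid, %d ROIs, seed %d\n",
              sum(x$counts), length(x$groups), length(x$sites),
              paste(x$shape, collapse = "x"), x$n_roi, x$seed))
  invisible(x)
}

#' Simulate a multi-subject T1w/T2w phantom cohort
#'
#' Realizes a [cohort_spec()]: one shared head geometry; per-site bias-field
#' draws and global intensity scales (the scanner differences the site
#' regressor must absorb); per-subject group effects, a linear age trend on
#' the GM ratio, independent acquisition noise, and a small random rigid
#' T2w misalignment. Full ground truth is kept for every subject.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, one T1w and one T2w
#'   NIfTI-1 volume per subject plus truth label volumes, the manifest CSV,
#'   the effect map CSV and the spec YAML are written there.
#' @param keep_volumes keep the simulated volumes in memory (default when
#'   not writing to disk); `cohort$subjects[[i]]` then holds `t1`, `t2`,
#'   `truth`.
#' @return list of class `phantom_cohort`: `manifest` (tibble: subject_id,
#'   group, age, site, seed, file paths when written), `subjects`,
#'   `truth_base` (shared geometry truth), `spec`.
#' @export
simulate_cohort <- function(spec, out_dir = NULL,
                            keep_volumes = is.null(out_dir)) {
  stopifnot(inherits(spec, "cohort_spec"))
  write <- !is.null(out_dir)
  if (write && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)

  ph <- make_brain_phantom(spec$shape, spec$spacing, spec$geometry,
                           spec$tissue_means, spec$n_roi, spec$seed)
  truth0 <- ph$truth
  truth0$effect_map <- spec$effect_map
  truth0$noise_sigma <- spec$noise$sigma

  n_total <- sum(spec$counts)
  seeds <- derive_seeds(spec$seed, n_total + 4 * length(spec$sites))
  site_seed <- seeds[seq_along(spec$sites)]
  subj_seed <- seeds[length(spec$sites) + seq_len(n_total)]
  aux_seed <- seeds[length(spec$sites) + n_total + seq_len(3 * length(spec$sites))]

  site_fields <- lapply(seq_along(spec$sites), function(s)
    draw_bias_fields(spec$shape, spec$spacing, spec$bias_strength, site_seed[s]))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(aux_seed[1])
  site_scale_t1 <- exp(rnorm(length(spec$sites), 0, spec$site_scale_sdlog))
  site_scale_t2 <- exp(rnorm(length(spec$sites), 0, spec$site_scale_sdlog))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  gm <- truth0$tissue_labels == 1L
  rows <- list(); subjects <- list(); si <- 0L
  for (s in seq_along(spec$sites)) {
    for (g in seq_along(spec$groups)) {
      ng <- spec$counts[spec$groups[g], spec$sites[s]]
      if (ng < 1) next
      ap <- spec$age_params[spec$age_params$group == spec$groups[g], ]
      for (k in seq_len(ng)) {
        si <- si + 1L
        sid <- sprintf("S%03d", si)
        sseed <- subj_seed[si]
        local_old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
        set.seed(sseed)
        age <- max(20, min(75, rnorm(1, ap$mean, ap$sd)))
        rot <- pmax(-3 * spec$misalign$rot_sd,
                    pmin(3 * spec$misalign$rot_sd, rnorm(3, 0, spec$misalign$rot_sd)))
        tra <- pmax(-3 * spec$misalign$trans_sd,
                    pmin(3 * spec$misalign$trans_sd, rnorm(3, 0, spec$misalign$trans_sd)))
        if (!is.null(local_old)) assign(".Random.seed", local_old, envir = globalenv())

        t2s <- apply_group_effect(ph$t2, truth0, spec$groups[g])
        agem <- 1 + spec$age_slope * (age - spec$ref_age)
        d2 <- t2s$data
        d2[gm] <- d2[gm] / agem        # ratio picks up the age multiplier
        t2s <- vol_like(ph$t2, d2, allow_na = FALSE)
        t1s <- vol_like(ph$t1, ph$t1$data * site_scale_t1[s], allow_na = FALSE)
        t2s <- vol_like(ph$t2, t2s$data * site_scale_t2[s], allow_na = FALSE)

        tr <- truth0
        tr$receive_field <- site_fields[[s]]$receive
        tr$transmit_field_t1 <- site_fields[[s]]$transmit_t1
        tr$transmit_field_t2 <- site_fields[[s]]$transmit_t2
        obs <- apply_bias_and_noise(t1s, t2s, tr, seed = sseed,
                                    noise = spec$noise$type)
        rigid <- rigid_transform(rot, tra,
                                 center = (dim(ph$t1$data) - 1) / 2 * spec$spacing)
        tr$true_rigid <- rigid
        t2m <- apply_misalignment(obs$t2_obs, rigid)
        t2m$data[is.na(t2m$data)] <- 0

        row <- tibble::tibble(subject_id = sid, group = spec$groups[g],
                              age = age, site = spec$sites[s], seed = sseed,
                              qc_excluded = FALSE, qc_reason = NA_character_)
        if (write) {
          p1 <- file.path(out_dir, paste0(sid, "_t1w.nii.gz"))
          p2 <- file.path(out_dir, paste0(sid, "_t2w.nii.gz"))
          write_volume(obs$t1_obs, p1)
          write_volume(t2m, p2)
          row$t1w_path <- p1; row$t2w_path <- p2
        }
        rows[[si]] <- row
        if (keep_volumes)
          subjects[[si]] <- list(subject_id = sid, t1 = obs$t1_obs, t2 = t2m,
                                 truth = tr)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$master_seed <- spec$seed
  if (write) {
    lab <- scalar_volume(array(as.numeric(truth0$tissue_labels), spec$shape),
                         spec$spacing)
    write_volume(lab, file.path(out_dir, "truth_tissue_labels.nii.gz"))
    roi <- scalar_volume(array(as.numeric(truth0$roi_labels), spec$shape),
                         spec$spacing)
    write_volume(roi, file.path(out_dir, "truth_roi_labels.nii.gz"))
    hm <- scalar_volume(array(as.numeric(truth0$head_mask), spec$shape),
                        spec$spacing)
    write_volume(hm, file.path(out_dir, "truth_head_mask.nii.gz"))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(spec$effect_map, file.path(out_dir, "effect_map.csv"),
              row.names = FALSE)
    write_cohort_spec(spec, file.path(out_dir, "cohort_spec.yaml"))
  }
  structure(list(manifest = manifest,
                 subjects = if (keep_volumes) subjects else NULL,
                 truth_base = truth0, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%s volumes in memory)\n",
              nrow(x$manifest), if (is.null(x$subjects)) "no" else "with"))
  print(dplyr::count(x$manifest, .data$group, .data$site))
  invisible(x)
}

#' Read / write a cohort spec as YAML
#'
#' @param spec a [cohort_spec()]; @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  y <- list(groups = spec$groups, sites = spec$sites,
            counts = apply(spec$counts, 1, as.list, simplify = FALSE),
            age_params = lapply(seq_len(nrow(spec$age_params)), function(i)
              as.list(spec$age_params[i, ])),
            age_slope = spec$age_slope, ref_age = spec$ref_age,
            site_scale_sdlog = spec$site_scale_sdlog,
            bias_strength = spec$bias_strength,
            effect_map = lapply(seq_len(nrow(spec$effect_map)), function(i)
              as.list(spec$effect_map[i, ])),
            noise = spec$noise, misalign = spec$misalign,
            shape = spec$shape, spacing = spec$spacing,
            geometry = spec$geometry,
            tissue_means = lapply(spec$tissue_means, as.list),
            n_roi = spec$n_roi, seed = spec$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  counts <- do.call(rbind, lapply(y$counts, unlist))
  rownames(counts) <- y$groups; colnames(counts) <- y$sites
  cohort_spec(groups = y$groups, sites = y$sites, counts = counts,
              age_params = dplyr::bind_rows(lapply(y$age_params, tibble::as_tibble)),
              age_slope = y$age_slope, ref_age = y$ref_age,
              site_scale_sdlog = y$site_scale_sdlog,
              bias_strength = y$bias_strength,
              effect_map = dplyr::bind_rows(lapply(y$effect_map, tibble::as_tibble)),
              noise = y$noise, misalign = y$misalign,
              shape = unlist(y$shape), spacing = unlist(y$spacing),
              geometry = lapply(y$geometry, unlist),
              tissue_means = lapply(y$tissue_means, unlist),
              n_roi = y$n_roi, seed = y$seed)
}
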