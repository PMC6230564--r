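#' Pipeline options for per-subject processing
#'
#' @param register run rigid T2w-to-T1w registration (disable only when the
#'   inputs are known to share a grid exactly).
#' @param reg_opts a [registration_options()] list; the default pipeline
#'   profile stops the pyramid at half resolution with a looser tolerance,
#'   which recovers the small scanner-frame offsets the phantoms carry at a
#'   fraction of the cost of a full-resolution polish.
#' @param norm_window,norm_fwhm local intensity normalization parameters
#'   ([local_intensity_normalize()]).
#' @param strip_opts a [skull_strip_options()] list.
#' @param fcm_beta spatial regularization weight of [fuzzy_segment()].
#' @param fcm_tol,fcm_max_iter fuzzy c-means convergence controls.
#' @param laplace_tol,laplace_max_iter depth solver controls.
#' @param band_halfwidth mid-depth band half-width `w`.
#' @param equivolume apply the volume-preserving depth reparameterization
#'   (global area proxies) before shell extraction.
#' @param shell_fwhm on-shell smoothing kernel FWHM in mm.
#' @param bias_sigma bias-field smoothing sigma in mm.
#' @param ratio_floor_quantile denominator floor quantile of
#'   [compute_ratio()].
#' @export
pipeline_options <- function(register = TRUE,
                             reg_opts = registration_options(levels = c(4, 2),
                                                             maxit = 1000,
                                                             reltol = 1e-5),
                             norm_window = 3L, norm_fwhm = 10,
                             strip_opts = skull_strip_options(),
                             fcm_beta = 0, fcm_tol = 1e-4, fcm_max_iter = 200L,
                             laplace_tol = 1e-5, laplace_max_iter = 5000L,
                             band_halfwidth = 0.1, equivolume = FALSE,
                             shell_fwhm = 6, bias_sigma = 5,
                             ratio_floor_quantile = 0.01) {
  list(register = register, reg_opts = reg_opts, norm_window = norm_window,
       norm_fwhm = norm_fwhm, strip_opts = strip_opts, fcm_beta = fcm_beta,
       fcm_tol = fcm_tol, fcm_max_iter = fcm_max_iter,
       laplace_tol = laplace_tol, laplace_max_iter = laplace_max_iter,
       band_halfwidth = band_halfwidth, equivolume = equivolume,
       shell_fwhm = shell_fwhm, bias_sigma = bias_sigma,
       ratio_floor_quantile = ratio_floor_quantile)
}

#' Run the full ratio pipeline on one subject
#'
#' Registration, normalization, cerebrum masking, GM/WM fuzzy segmentation,
#' Laplace depth, mid-depth shell extraction with ROI label transfer,
#' square-root-product bias correction, ratio formation and on-shell
#' smoothing. The locally normalized image is used exclusively for masking
#' and segmentation; the bias estimate, correction and ratio consume the
#' original (registered) intensities.
#'
#' @param t1,t2 observed [scalar_volume()]s (T2w possibly misaligned).
#' @param head_mask logical array covering brain plus dura (for phantoms,
#'   from the ground truth, standing in for a template-propagated mask).
#' @param roi_labels integer array of ROI labels over GM.
#' @param opts a [pipeline_options()] list.
#' @return object of class `subject_result`: `shell_table` (tibble: voxel
#'   linear index, `roi_id`, `value` = smoothed ratio), `mean_cortical`
#'   (mean smoothed mid-depth ratio), `transform` (recovered rigid, or
#'   `NULL`), `cerebrum`, `gm_mask`, `wm_mask`, `depth`, `shell`, `ratio`,
#'   `bias`, `seg`.
#' @export
process_subject <- function(t1, t2, head_mask, roi_labels,
                            opts = pipeline_options()) {
  stopifnot(is_scalar_volume(t1), is_scalar_volume(t2))
  head_mask <- as_mask_array(head_mask)

  transform <- NULL
  t2r <- t2
  if (opts$register) {
    reg <- rigid_register(t2, t1, opts$reg_opts)
    transform <- reg$transform
    t2r <- resample(t2, transform, reference = t1)
    t2r$data[is.na(t2r$data)] <- 0
  }

  norm <- local_intensity_normalize(t1, opts$norm_window, opts$norm_fwhm,
                                    mask = head_mask)
  cerebrum <- skull_strip(norm, head_mask, threshold = NULL, opts$strip_opts)
  seg <- fuzzy_segment(norm, cerebrum, n_classes = 2L,
                       spatial_beta = opts$fcm_beta, tol = opts$fcm_tol,
                       max_iter = opts$fcm_max_iter)
  gm_mask <- seg$hard_labels == 1L
  wm_mask <- seg$hard_labels == 2L

  depth <- solve_laplace_depth(gm_mask, wm_mask, outside_mask = NULL,
                               spacing = t1$spacing, tol = opts$laplace_tol,
                               max_iter = opts$laplace_max_iter,
                               on_topology = "drop")
  if (opts$equivolume) {
    pr <- estimate_area_proxies(depth$gm_mask, wm_mask, spacing = t1$spacing)
    depth <- equivolume_fraction(depth, pr$inner, pr$outer)
  }
  shell <- extract_middepth_shell(depth, opts$band_halfwidth, roi_labels)

  bias <- estimate_bias_field(t1, t2r, cerebrum, opts$bias_sigma)
  t1c <- correct_bias(t1, bias)
  t2c <- correct_bias(t2r, bias)
  ratio <- compute_ratio(t1c, t2c, cerebrum, opts$ratio_floor_quantile)
  sm <- smooth_on_shell(ratio$data, shell, opts$shell_fwhm)

  idx <- which(shell$mask)
  shell_table <- tibble::tibble(voxel = idx,
                                roi_id = shell$roi[idx],
                                value = sm[idx])
  structure(list(shell_table = shell_table,
                 mean_cortical = mean(sm[idx], na.rm = TRUE),
                 transform = transform, cerebrum = cerebrum,
                 gm_mask = gm_mask, wm_mask = wm_mask, depth = depth,
                 shell = shell, ratio = ratio, bias = bias, seg = seg),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %d shell voxels, mean mid-depth ratio %.4f\n",
              nrow(x$shell_table), x$mean_cortical))
  invisible(x)
}

#' Process every subject of a simulated (or on-disk) cohort
#'
#' Runs [process_subject()] per subject and assembles the per-subject,
#' per-ROI signal table plus the subject-level mean cortical ratios the QC
#' rule operates on.
#'
#' @param cohort a `phantom_cohort` from [simulate_cohort()] (in-memory
#'   volumes), or a manifest tibble with `t1w_path`/`t2w_path` columns plus
#'   `truth_dir` pointing at the written truth volumes.
#' @param opts a [pipeline_options()] list.
#' @param truth_dir directory holding `truth_head_mask.nii.gz` and
#'   `truth_roi_labels.nii.gz` when `cohort` is a manifest of file paths.
#' @param keep_subject_results keep the full per-subject result objects
#'   (memory-heavy; off by default).
#' @return list of class `cohort_result`: `roi_table`
#'   ([build_roi_table()] output), `subjects` (manifest with
#'   `mean_signal`), `shell_values` (subjects x shell-voxel matrix on the
#'   ground-truth shell ordering of each subject's own shell table is not
#'   guaranteed identical, so the matrix is filled by voxel index),
#'   `results` (when kept).
#' @export
run_cohort_pipeline <- function(cohort, opts = pipeline_options(),
                                truth_dir = NULL,
                                keep_subject_results = FALSE) {
  if (inherits(cohort, "phantom_cohort")) {
    manifest <- cohort$manifest
    get_subject <- function(i) cohort$subjects[[i]]
    head_mask <- cohort$truth_base$head_mask
    roi_labels <- cohort$truth_base$roi_labels
    n_roi <- cohort$truth_base$n_roi
    if (is.null(cohort$subjects))
      stop("cohort has no in-memory volumes; pass the manifest with truth_dir instead",
           call. = FALSE)
  } else {
    manifest <- tibble::as_tibble(cohort)
    stopifnot(!is.null(truth_dir))
    head_mask <- read_volume(file.path(truth_dir, "truth_head_mask.nii.gz"))$data > 0
    roiv <- read_volume(file.path(truth_dir, "truth_roi_labels.nii.gz"))
    roi_labels <- array(as.integer(round(roiv$data)), dim(roiv$data))
    n_roi <- max(roi_labels)
    get_subject <- function(i) list(t1 = read_volume(manifest$t1w_path[i]),
                                    t2 = read_volume(manifest$t2w_path[i]))
  }
  n <- nrow(manifest)
  tabs <- vector("list", n)
  means <- numeric(n)
  full <- if (keep_subject_results) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sub <- get_subject(i)
    res <- process_subject(sub$t1, sub$t2, head_mask, roi_labels, opts)
    tabs[[i]] <- dplyr::mutate(res$shell_table,
                               subject_id = manifest$subject_id[i])
    means[i] <- res$mean_cortical
    if (keep_subject_results) full[[i]] <- res
  }
  long <- dplyr::bind_rows(tabs)
  subjects <- dplyr::mutate(manifest, mean_signal = means)
  structure(list(roi_table = build_roi_table(long, n_roi = n_roi),
                 subjects = subjects,
                 shell_long = long,
                 results = full),
            class = "cohort_result")
}

#' QC-filter and fit the group model for a processed cohort
#'
#' Applies the gain-difference exclusion rule to the subject-level mean
#' cortical ratios, then fits the per-ROI weighted regression with
#' Holm-Bonferroni correction.
#'
#' @param cohort_result a `cohort_result` from [run_cohort_pipeline()].
#' @param alpha significance level.
#' @param k QC exclusion multiplier.
#' @param ... passed to [fit_roi_wls()].
#' @return list of class `cohort_analysis`: `fit` (a `roi_fit`), `subjects`
#'   (with QC flags), `n_excluded`.
#' @export
analyze_cohort <- function(cohort_result, alpha = 0.05, k = 1.5, ...) {
  subjects <- qc_exclude(cohort_result$subjects, value = "mean_signal", k = k)
  fit <- fit_roi_wls(cohort_result$roi_table, subjects, alpha = alpha, ...)
  structure(list(fit = fit, subjects = subjects,
                 n_excluded = sum(subjects$qc_excluded)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects (%d QC-excluded)\n",
              nrow(x$subjects), x$n_excluded))
  print(x$fit)
  invisible(x)
}
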