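#' Plot an axial slice of a volume
#'
#' @param vol a [scalar_volume()] (or bare 3D array).
#' @param slice slice index along the third axis (middle by default).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_volume_slice <- function(vol, slice = NULL, title = NULL) {
  arr <- as_vol_array(vol)
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Effect-size plot of per-ROI group coefficients
#'
#' Coefficients (ratio units, relative to the reference group) per ROI and
#' group level, with Holm-significant effects highlighted.
#'
#' @param object a `roi_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roi_fit <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_id, .data$estimate,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std_error,
      ymax = .data$estimate + .data$std_error), linewidth = 0.3, size = 0.2) +
    ggplot2::facet_wrap(~term) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "ROI", y = "coefficient (ratio units vs reference)",
                  colour = "Holm-significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Depth profile across the cortical ribbon
#'
#' Histogram of normalized depth values; flat for a well-resolved ribbon.
#'
#' @param depth a `depth_map`.
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_depth_profile <- function(depth, bins = 30) {
  d <- depth$depth[depth$gm_mask]
  ggplot2::ggplot(tibble::tibble(depth = d), ggplot2::aes(.data$depth)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "normalized cortical depth", y = "voxels") +
    ggplot2::theme_minimal()
}
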