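#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ADC histogram fit
#'
#' Tumor ADC histogram (density scale) with the fitted two-Gaussian mixture,
#' its components, the derived ADC_L and the classification cutoff.
#'
#' @param object An `adc_fit` from [fit_adc_double_gaussian()].
#' @param cutoff Cutoff line to draw (um^2/s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adc_fit <- function(object, cutoff = 1240, ...) {
  stopifnot(!is.null(object$breaks))
  mids <- (object$breaks[-1] + object$breaks[-length(object$breaks)]) / 2
  hist_df <- tibble::tibble(adc = mids, density = object$density)
  grid <- tibble::tibble(adc = seq(min(object$breaks), max(object$breaks),
                                   length.out = 400))
  grid$low <- object$w_lo * stats::dnorm(grid$adc, object$mu_lo,
                                         object$sigma_lo)
  grid$high <- object$w_hi * stats::dnorm(grid$adc, object$mu_hi,
                                          object$sigma_hi)
  grid$mixture <- grid$low + grid$high
  comp <- tidyr::pivot_longer(grid, c("low", "high", "mixture"),
                              names_to = "component", values_to = "density")
  ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$adc)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), width = diff(mids[1:2]),
                      fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component,
                                    linetype = .data$component)) +
    ggplot2::geom_vline(xintercept = object$adc_l, colour = "#2166AC") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2) +
    ggplot2::labs(x = "ADC (µm²/s)", y = "density",
                  title = sprintf("ADC_L = %.0f µm²/s", object$adc_l)) +
    ggplot2::theme_minimal()
}

#' Plot a phenotype clustering
#'
#' Scatter of lesions in two of the clustering features, coloured by k-means
#' cluster and shaped by cutoff phenotype; discordant lesions stand out as
#' colour/shape mismatches.
#'
#' @param object A `phenotype_clusters` from [kmeans_phenotype_cluster()].
#' @param data The cohort table the clustering was run on.
#' @param x,y Feature columns to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenotype_clusters <- function(object, data, x = "adc_l",
                                        y = "median_rcbv", ...) {
  df <- tibble::as_tibble(data)[object$assignments$row, ]
  df$cluster <- factor(object$assignments$cluster)
  df$phenotype <- object$assignments$phenotype
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                   colour = .data$cluster,
                                   shape = .data$phenotype)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::geom_vline(xintercept = 1240, linetype = 2, colour = "grey40") +
    ggplot2::labs(title = sprintf("k-means concordance %.2f",
                                  object$concordance)) +
    ggplot2::theme_minimal()
}

#' Group comparison panels for the MRI metrics
#'
#' Jittered points with group medians for each MRI metric, split by
#' diffusion phenotype — the cohort-level view of the group differences.
#'
#' @param cohort Lesion-profile tibble.
#' @param metrics Metric columns to show.
#' @return A ggplot (facetted).
#' @export
plot_group_comparisons <- function(cohort,
                                   metrics = c("volume_cc", "median_deltat1",
                                               "median_rcbv",
                                               "median_mtr_asym",
                                               "median_qt2",
                                               "median_qt2star")) {
  metrics <- intersect(metrics, names(cohort))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(cohort)[c("phenotype", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phenotype, y = .data$value,
                                     colour = .data$phenotype)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "black", linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "ADC_L phenotype", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mid-axial slice of a map with optional mask outline
#'
#' @param vol An [image_volume()].
#' @param mask Optional [binary_mask()] whose outline is overlaid.
#' @param slice Slice index (default: middle of the third axis).
#' @return A ggplot.
#' @export
plot_map_slice <- function(vol, mask = NULL, slice = NULL) {
  d <- dim(vol$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(vol$data[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    md <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
    md$inside <- as.numeric(mask$data[, , slice])
    p <- p + ggplot2::geom_contour(data = md,
                                   ggplot2::aes(z = .data$inside),
                                   breaks = 0.5, colour = "red",
                                   inherit.aes = FALSE)
  }
  p
}
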