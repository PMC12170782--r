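#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ADC double-Gaussian fit
#'
#' @param x An `adc_fit` from [fit_adc_double_gaussian()].
#' @param ... Unused.
#' @return Tibble with one row per mixture component (`component`, `weight`,
#'   `mean`, `sd`).
#' @export
tidy.adc_fit <- function(x, ...) {
  tibble::tibble(component = c("low", "high"),
                 weight = c(x$w_lo, x$w_hi),
                 mean = c(x$mu_lo, x$mu_hi),
                 sd = c(x$sigma_lo, x$sigma_hi))
}

#' Glance at an ADC double-Gaussian fit
#'
#' @inheritParams tidy.adc_fit
#' @return One-row tibble: `adc_l`, `n_voxels`, `converged`,
#'   `collapsed_to_single`, `rss`.
#' @export
glance.adc_fit <- function(x, ...) {
  tibble::tibble(adc_l = x$adc_l, n_voxels = x$n_voxels,
                 converged = x$converged,
                 collapsed_to_single = x$collapsed_to_single, rss = x$rss)
}

#' Tidy a leakage fit
#'
#' @param x A `leakage_fit` from [fit_bidirectional_leakage()].
#' @param ... Unused.
#' @return One-row tibble of the fitted parameters.
#' @export
tidy.leakage_fit <- function(x, ...) {
  tibble::tibble(k1 = x$k1, k2 = x$k2, kep = x$kep, rss = x$rss)
}

#' Tidy the qT2-adjusted regression
#'
#' Coefficient-level summary of the underlying OLS fit.
#'
#' @param x An `adjusted_regression`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.adjusted_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' @rdname tidy.adjusted_regression
#' @return For `glance()`: one-row tibble `beta_group`, `p_group`, `r2`, `n`.
#' @export
glance.adjusted_regression <- function(x, ...) x$summary

#' Tidy a phenotype clustering
#'
#' @param x A `phenotype_clusters` from [kmeans_phenotype_cluster()].
#' @param ... Unused.
#' @return The per-lesion assignment tibble.
#' @export
tidy.phenotype_clusters <- function(x, ...) x$assignments

#' @rdname tidy.phenotype_clusters
#' @return For `glance()`: one-row tibble with `concordance`,
#'   `n_discordant`, `n`, `seed`.
#' @export
glance.phenotype_clusters <- function(x, ...) {
  tibble::tibble(concordance = x$concordance,
                 n_discordant = x$n_discordant,
                 n = nrow(x$assignments), seed = x$seed)
}

#' Tidy a Pearson correlation matrix
#'
#' @param x A `pearson_matrix`.
#' @param ... Unused.
#' @return Long tibble with one row per variable pair: `var1`, `var2`, `r`,
#'   `p_value`, `n`.
#' @export
tidy.pearson_matrix <- function(x, ...) {
  nm <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                 r = x$r[idx], p_value = x$p[idx], n = x$n[idx])
}

#' Glance at a cohort report
#'
#' @param x A `cohort_report` from [analyze_cohort()].
#' @param ... Unused.
#' @return One-row tibble summarizing the analysis: lesion count, numbers of
#'   significant comparisons before/after BH, clustering concordance.
#' @export
glance.cohort_report <- function(x, ...) {
  cmp <- x$comparisons[x$comparisons$family == "mri_metrics", ]
  tibble::tibble(
    n_lesions = x$n_lesions,
    n_metric_tests = nrow(cmp),
    n_sig_raw = sum(cmp$p_raw <= x$alpha),
    n_sig_adj = sum(cmp$reject),
    cluster_concordance = if (!is.null(x$clusters))
      x$clusters$concordance else NA_real_)
}
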