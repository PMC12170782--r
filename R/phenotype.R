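#' Double-Gaussian fit of a tumor ADC histogram
#'
#' The core phenotyping statistic: the ADC values inside the
#' contrast-enhancing tumor are binned into a density-normalized histogram
#' (default 50 um^2/s bins over 0-4000 um^2/s) and modelled as a two-Gaussian
#' mixture `f(x) = w_lo * N(mu_lo, sigma_lo) + w_hi * N(mu_hi, sigma_hi)`
#' fitted by bounded nonlinear least squares, initialized from the 25th/75th
#' percentiles. `ADC_L` is the mean of the lower-mean component. When the two
#' components collapse (separation < `collapse_sep` um^2/s or a weight below
#' `collapse_w`), a single Gaussian is refit and its mean taken as `ADC_L`.
#'
#' An expectation-maximization fit on the raw values (`method = "em"`, via
#' \pkg{mclust}) is offered as a cross-check; the two agree closely on
#' well-separated mixtures.
#'
#' @param adc_values Numeric vector of tumor ADC values in um^2/s
#'   (>= `min_values` finite values required).
#' @param bin_width Histogram bin width in um^2/s.
#' @param range Histogram range in um^2/s.
#' @param min_values Minimum number of finite values.
#' @param collapse_sep,collapse_w Degenerate-fit thresholds.
#' @param method `"histogram"` (default) or `"em"`.
#' @return Object of class `adc_fit`: `w_lo`, `mu_lo`, `sigma_lo`, `w_hi`,
#'   `mu_hi`, `sigma_hi`, `adc_l`, `n_voxels`, `converged`,
#'   `collapsed_to_single`, `rss`.
#' @export
fit_adc_double_gaussian <- function(adc_values, bin_width = 50,
                                    range = c(0, 4000), min_values = 100,
                                    collapse_sep = 100, collapse_w = 0.02,
                                    method = c("histogram", "em")) {
  method <- match.arg(method)
  x <- adc_values[is.finite(adc_values)]
  if (length(x) < min_values) {
    stop("fit_adc_double_gaussian: only ", length(x),
         " finite ADC values (need >= ", min_values, ")")
  }
  x <- x[x >= range[1] & x <= range[2]]
  if (method == "em") {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      stop("method = 'em' requires the mclust package")
    }
    # Mclust resolves mclustBIC in the caller's frame; bind it locally
    mclustBIC <- mclust::mclustBIC
    em <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    ord <- order(em$parameters$mean)
    pars <- list(w = em$parameters$pro[ord], mu = em$parameters$mean[ord],
                 sigma = sqrt(em$parameters$variance$sigmasq[ord]))
    return(new_adc_fit(pars$w[1], pars$mu[1], pars$sigma[1], pars$mu[2],
                       pars$sigma[2], length(x), TRUE, FALSE, NA_real_,
                       breaks = NULL, density = NULL))
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  dens <- h$density
  q <- stats::quantile(x, c(0.25, 0.75))
  s0 <- max(stats::sd(x) / 2, bin_width)
  start <- list(w = 0.5, mu1 = unname(q[1]), s1 = s0,
                mu2 = unname(q[2]), s2 = s0)
  lower <- c(w = 0.01, mu1 = range[1], s1 = bin_width / 2,
             mu2 = range[1], s2 = bin_width / 2)
  upper <- c(w = 0.99, mu1 = range[2], s1 = diff(range) / 2,
             mu2 = range[2], s2 = diff(range) / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ w * stats::dnorm(mids, mu1, s1) +
        (1 - w) * stats::dnorm(mids, mu2, s2),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data; fall back to a single-Gaussian description
    return(new_adc_fit(1, mean(x), stats::sd(x), mean(x), stats::sd(x),
                       length(x), FALSE, TRUE, NA_real_, breaks, dens))
  }
  cf <- as.list(stats::coef(fit))
  if (cf$mu1 > cf$mu2) {  # enforce mu_lo <= mu_hi by swap
    cf <- list(w = 1 - cf$w, mu1 = cf$mu2, s1 = cf$s2, mu2 = cf$mu1,
               s2 = cf$s1)
  }
  rss <- sum(stats::resid(fit)^2)
  collapsed <- (cf$mu2 - cf$mu1) < collapse_sep ||
    min(cf$w, 1 - cf$w) < collapse_w
  if (collapsed) {
    single <- tryCatch(
      minpack.lm::nlsLM(dens ~ stats::dnorm(mids, mu, s),
                        start = list(mu = mean(x), s = stats::sd(x)),
                        lower = c(mu = range[1], s = bin_width / 2),
                        upper = c(mu = range[2], s = diff(range))),
      error = function(e) NULL)
    if (!is.null(single)) {
      sc <- as.list(stats::coef(single))
      return(new_adc_fit(1, sc$mu, sc$s, sc$mu, sc$s, length(x), TRUE, TRUE,
                         sum(stats::resid(single)^2), breaks, dens))
    }
    return(new_adc_fit(1, mean(x), stats::sd(x), mean(x), stats::sd(x),
                       length(x), TRUE, TRUE, rss, breaks, dens))
  }
  new_adc_fit(cf$w, cf$mu1, cf$s1, cf$mu2, cf$s2, length(x), TRUE, FALSE,
              rss, breaks, dens)
}

new_adc_fit <- function(w_lo, mu_lo, sigma_lo, mu_hi, sigma_hi, n, converged,
                        collapsed, rss, breaks, density) {
  structure(list(
    w_lo = w_lo, mu_lo = mu_lo, sigma_lo = sigma_lo,
    w_hi = 1 - w_lo, mu_hi = mu_hi, sigma_hi = sigma_hi,
    adc_l = mu_lo, n_voxels = n, converged = converged,
    collapsed_to_single = collapsed, rss = rss,
    breaks = breaks, density = density), class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf(
    "<adc_fit> ADC_L = %.0f um^2/s (%s), n = %d voxels\n",
    x$adc_l, if (x$collapsed_to_single) "single Gaussian" else
      sprintf("w_lo = %.2f, mu = %.0f/%.0f", x$w_lo, x$mu_lo, x$mu_hi),
    x$n_voxels))
  invisible(x)
}

#' Diffusion phenotype from ADC_L
#'
#' `"high"` when `adc_l >= cutoff` (boundary inclusive), `"low"` otherwise.
#' The default cutoff of 1240 um^2/s is the externally validated threshold
#' separating diffusion phenotypes predictive of anti-VEGF benefit.
#'
#' @param adc_l ADC_L value(s) in um^2/s.
#' @param cutoff Classification cutoff in um^2/s.
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_phenotype <- function(adc_l, cutoff = 1240) {
  if (any(!is.finite(adc_l))) {
    stop("classify_phenotype: non-finite ADC_L value")
  }
  ifelse(adc_l >= cutoff, "high", "low")
}

#' RANO measurability of a tumor mask
#'
#' Operationalized as the mask's axis-aligned bounding box spanning at least
#' 10 mm along all three axes (a bounding-box stand-in for the >= 1 cm
#' orthogonal-diameter rule).
#'
#' @param tumor Tumor [binary_mask()].
#' @param min_mm Minimum required span in mm (default 10).
#' @return Logical flag.
#' @export
check_rano_measurable <- function(tumor, min_mm = 10) {
  stopifnot(inherits(tumor, "binary_mask"))
  if (!any(tumor$data)) {
    warning("check_rano_measurable: empty tumor mask")
    return(FALSE)
  }
  idx <- which(tumor$data, arr.ind = TRUE)
  spans <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * tumor$spacing
  all(spans >= min_mm)
}

#' Per-lesion multiparametric profile
#'
#' Extracts the lesion's row of the cohort table: the double-Gaussian ADC_L
#' and phenotype, ROI medians of every supplied map over valid (finite)
#' tumor voxels, the contrast-enhancing volume in cc, RANO measurability,
#' and any clinical covariates passed through.
#'
#' @param maps Named list of [image_volume()]s; recognized names are `adc`,
#'   `rcbv`, `mtr_asym`, `qt2`, `qt2star`, `deltat1`. Missing maps yield
#'   missing fields.
#' @param tumor Tumor [binary_mask()] (nonempty).
#' @param clinical Optional named list or one-row data frame of covariates
#'   (e.g. `lesion_id`, `location`, `sex`, `mgmt`, `egfr`,
#'   `steroid_dose_mg`, `age`); carried into the output unchanged.
#' @param cutoff ADC_L classification cutoff in um^2/s.
#' @param ... Passed to [fit_adc_double_gaussian()].
#' @return One-row tibble (a LesionProfile) with the ADC fit attached as
#'   attribute `"adc_fit"`.
#' @export
extract_lesion_profile <- function(maps, tumor, clinical = NULL,
                                   cutoff = 1240, ...) {
  stopifnot(inherits(tumor, "binary_mask"))
  if (!any(tumor$data)) stop("extract_lesion_profile: empty tumor mask")
  med <- function(name) {
    if (is.null(maps[[name]])) return(NA_real_)
    v <- suppressWarnings(masked_values(maps[[name]], tumor))
    if (length(v) == 0) NA_real_ else stats::median(v)
  }
  voxel_cc <- prod(tumor$spacing) / 1000  # mm^3 -> cc
  fit <- NULL
  adc_l <- NA_real_
  phen <- NA_character_
  if (!is.null(maps$adc)) {
    vals <- suppressWarnings(masked_values(maps$adc, tumor))
    fit <- fit_adc_double_gaussian(vals, ...)
    adc_l <- fit$adc_l
    phen <- classify_phenotype(adc_l, cutoff)
  }
  out <- tibble::tibble(
    adc_l = adc_l, phenotype = phen,
    median_rcbv = med("rcbv"), median_mtr_asym = med("mtr_asym"),
    median_qt2 = med("qt2"), median_qt2star = med("qt2star"),
    median_deltat1 = med("deltat1"),
    volume_cc = sum(tumor$data) * voxel_cc,
    rano_measurable = check_rano_measurable(tumor))
  if (!is.null(clinical)) {
    cl <- tibble::as_tibble(as.list(clinical))
    out <- dplyr::bind_cols(cl[setdiff(names(cl), names(out))], out)
  }
  attr(out, "adc_fit") <- fit
  out
}

#' Group frequency maps of lesion masks
#'
#' Voxelwise mean of the binary tumor masks per phenotype group: the value at
#' a voxel is the fraction of that group's lesions covering it. The group
#' maps, weighted by group sizes, sum to the overall frequency map.
#'
#' @param masks List of tumor [binary_mask()]s in a common grid.
#' @param phenotypes Character vector (`"high"`/`"low"`), one per mask.
#' @return Named list of two [image_volume()]s (`high`, `low`); groups with
#'   no lesions are omitted.
#' @export
compute_frequency_map <- function(masks, phenotypes) {
  stopifnot(length(masks) == length(phenotypes), length(masks) >= 1)
  for (m in masks[-1]) assert_same_grid(masks[[1]], m, "lesion masks")
  out <- list()
  for (g in c("high", "low")) {
    sel <- which(phenotypes == g)
    if (length(sel) == 0) next
    acc <- Reduce(`+`, lapply(masks[sel], function(m) m$data * 1))
    out[[g]] <- image_volume(acc / length(sel),
                             spacing = masks[[1]]$spacing,
                             frame_id = masks[[1]]$frame_id)
  }
  out
}
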