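#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test: exact enumeration when both groups have at
#' most `exact_max` observations and no ties, otherwise the normal
#' approximation with tie and continuity correction (the standard
#' [stats::wilcox.test()] machinery). Identical values across both groups
#' yield `p = 1` with a warning.
#'
#' @param values_high,values_low Numeric vectors (nonempty).
#' @param metric Optional metric name carried into the output.
#' @param family Multiplicity family label (see [bh_adjust()]).
#' @param exact_max Largest group size for exact enumeration (default 8).
#' @return One-row tibble: `metric`, `n_high`, `n_low`, `median_high`,
#'   `median_low`, `u_stat`, `p_raw`, `family`.
#' @export
mann_whitney <- function(values_high, values_low, metric = NA_character_,
                         family = NA_character_, exact_max = 8) {
  x <- values_high[is.finite(values_high)]
  y <- values_low[is.finite(values_low)]
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney: both groups must be nonempty")
  }
  if (length(unique(c(x, y))) == 1L) {
    warning("mann_whitney: all values identical; p = 1")
    u <- length(x) * length(y) / 2
    p <- 1
  } else {
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    u <- unname(wt$statistic)
    p <- min(wt$p.value, 1)
  }
  tibble::tibble(metric = metric, n_high = length(x), n_low = length(y),
                 median_high = stats::median(x), median_low = stats::median(y),
                 u_stat = u, p_raw = p, family = family)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method (the sum of the
#' probabilities of all tables no more likely than the observed one), i.e.
#' the [stats::fisher.test()] convention. The reported odds ratio is the
#' sample cross-product `(a d) / (b c)`; a zero margin gives `p = 1` with an
#' undefined odds ratio and a flag.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param label Optional test label.
#' @param family Multiplicity family label.
#' @return One-row tibble: `label`, `a`..`d`, `odds_ratio`, `p_raw`,
#'   `degenerate`, `family`.
#' @export
fisher_exact <- function(table, label = NA_character_,
                         family = NA_character_) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("fisher_exact: need a 2x2 table of nonnegative integer counts")
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("fisher_exact: zero margin; p = 1, odds ratio undefined")
    p <- 1
    or <- NA_real_
  } else {
    p <- stats::fisher.test(tab)$p.value
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  tibble::tibble(label = label, a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
                 d = tab[2, 2], odds_ratio = or, p_raw = min(p, 1),
                 degenerate = degenerate, family = family)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted p-values with monotonicity enforcement
#' ([stats::p.adjust()] with `method = "BH"`); a test is rejected when its
#' adjusted p-value is at or below `alpha`.
#'
#' @param p_values Raw p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Tibble with `p_raw`, `p_adj`, `reject`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_adj = adj, reject = adj <= alpha)
}

#' qT2-adjusted group regression of MTR_asym
#'
#' Ordinary least squares `mtr ~ intercept + 1[phenotype == high] + qt2` on
#' complete cases, testing whether the amine CEST contrast differs between
#' diffusion phenotypes after adjusting for the tissue-T2 dependence of
#' MTR_asym. A zero-variance covariate is dropped with a warning.
#'
#' @param mtr MTR_asym medians (percent).
#' @param phenotype Character `"high"`/`"low"` labels.
#' @param qt2 qT2 medians (ms).
#' @return Object of class `adjusted_regression`: tibble `summary` with
#'   `beta_group` (percent units), `p_group`, `r2`, `n`, plus the underlying
#'   `lm` fit.
#' @export
adjusted_group_regression <- function(mtr, phenotype, qt2) {
  df <- data.frame(mtr = mtr, grp = factor(phenotype, c("low", "high")),
                   qt2 = qt2)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_dropped <- length(mtr) - nrow(df)
  if (n_dropped > 0) vlog("adjusted_group_regression: dropped ", n_dropped,
                          " incomplete cases")
  if (nrow(df) < 3) stop("adjusted_group_regression: fewer than 3 complete cases")
  if (length(unique(df$grp)) < 2) {
    stop("adjusted_group_regression: only one phenotype present")
  }
  if (stats::var(df$qt2) == 0) {
    warning("adjusted_group_regression: zero-variance qT2; covariate dropped")
    fit <- stats::lm(mtr ~ grp, data = df)
  } else {
    fit <- stats::lm(mtr ~ grp + qt2, data = df)
  }
  sm <- summary(fit)
  co <- sm$coefficients["grphigh", ]
  structure(list(
    summary = tibble::tibble(beta_group = unname(co["Estimate"]),
                             p_group = unname(co["Pr(>|t|)"]),
                             r2 = sm$r.squared, n = nrow(df)),
    fit = fit), class = "adjusted_regression")
}

#' @export
print.adjusted_regression <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<adjusted_regression> beta_group = %.3f%%, p = %.3g, R^2 = %.3f, n = %d\n",
    s$beta_group, s$p_group, s$r2, s$n))
  invisible(x)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the numeric columns of a
#' data frame, with per-pair two-sided p-values. Zero-variance columns give
#' `NA` entries with a warning.
#'
#' @param data Data frame of numeric columns.
#' @return Object of class `pearson_matrix`: `r`, `p`, `n` matrices.
#' @export
pearson_matrix <- function(data) {
  data <- as.data.frame(data)[vapply(data, is.numeric, TRUE)]
  k <- ncol(data)
  stopifnot(k >= 2)
  nm <- names(data)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      cc <- stats::complete.cases(data[[i]], data[[j]])
      n[i, j] <- n[j, i] <- sum(cc)
      if (sum(cc) < 3 || stats::var(data[[i]][cc]) == 0 ||
          stats::var(data[[j]][cc]) == 0) {
        warning("pearson_matrix: degenerate pair ", nm[i], " / ", nm[j])
        next
      }
      ct <- stats::cor.test(data[[i]][cc], data[[j]][cc])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' k-means phenotype clustering of lesion-level MRI metrics
#'
#' z-score standardizes the per-lesion features (by default ADC_L as a
#' continuous measure, median rCBV and median MTR_asym), runs k-means with
#' k = 2 (50 restarts, fixed seed, best inertia kept), relabels so cluster 1
#' is the cluster with the higher mean ADC_L, and reports the concordance of
#' the cluster assignment with the cutoff-based phenotype groups.
#'
#' @param data Data frame with one row per lesion.
#' @param features Feature column names (complete cases required).
#' @param seed RNG seed.
#' @param nstart Number of k-means restarts.
#' @param cutoff ADC_L cutoff for the reference grouping.
#' @param adc_col Column holding ADC_L.
#' @return Object of class `phenotype_clusters`: per-lesion `assignments`
#'   tibble, standardized `centroids`, `concordance`, `n_discordant`, `seed`.
#' @export
kmeans_phenotype_cluster <- function(data,
                                     features = c("adc_l", "median_rcbv",
                                                  "median_mtr_asym"),
                                     seed = 42, nstart = 50, cutoff = 1240,
                                     adc_col = "adc_l") {
  data <- as.data.frame(data)
  stopifnot(all(features %in% names(data)))
  X <- data[features]
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  if (nrow(unique(X)) < 2) {
    stop("kmeans_phenotype_cluster: fewer than 2 distinct complete cases")
  }
  Z <- scale(as.matrix(X))
  km <- with_local_seed(seed,
                        stats::kmeans(Z, centers = 2, nstart = nstart,
                                      iter.max = 100))
  # relabel: cluster 1 = higher mean ADC_L
  m_adc <- tapply(X[[adc_col]], km$cluster, mean)
  relabel <- if (m_adc["1"] >= m_adc["2"]) c(1L, 2L) else c(2L, 1L)
  cluster <- relabel[km$cluster]
  centroids <- km$centers[order(relabel), , drop = FALSE]
  rownames(centroids) <- c("1", "2")
  phen <- classify_phenotype(X[[adc_col]], cutoff)
  concordant <- (cluster == 1L) == (phen == "high")
  assignments <- tibble::tibble(
    row = which(cc), cluster = cluster, phenotype = phen,
    concordant = concordant)
  if ("lesion_id" %in% names(data)) {
    assignments <- dplyr::bind_cols(
      tibble::tibble(lesion_id = data$lesion_id[cc]), assignments)
  }
  structure(list(assignments = assignments, centroids = centroids,
                 concordance = mean(concordant),
                 n_discordant = sum(!concordant), seed = seed,
                 features = features), class = "phenotype_clusters")
}

#' @export
print.phenotype_clusters <- function(x, ...) {
  cat(sprintf(
    "<phenotype_clusters> k = 2 on (%s): concordance %.3f (%d discordant of %d)\n",
    paste(x$features, collapse = ", "), x$concordance, x$n_discordant,
    nrow(x$assignments)))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Logs the normality of a sample; the pipeline always proceeds with
#' nonparametric group tests regardless (matching the analysis plan), so this
#' is a reporting device, not a branch.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `n`, `p_shapiro`, `normal` (NA when the gate
#'   cannot run).
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  v <- values[is.finite(values)]
  if (length(v) < 3) {
    warning("shapiro_gate: fewer than 3 values; gate skipped")
    return(tibble::tibble(n = length(v), p_shapiro = NA_real_, normal = NA))
  }
  if (stats::var(v) == 0) {
    warning("shapiro_gate: constant input; flag undefined")
    return(tibble::tibble(n = length(v), p_shapiro = NA_real_, normal = NA))
  }
  p <- stats::shapiro.test(v)$p.value
  tibble::tibble(n = length(v), p_shapiro = p, normal = p > alpha)
}
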