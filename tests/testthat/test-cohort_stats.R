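test_that("Mann-Whitney U matches exact enumeration on small groups", {
  # {1,2,3} vs {4,5,6}: U = 0; all 20 assignments equally likely -> p = 0.1
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_stat, 0)
  expect_equal(res$p_raw, 0.1, tolerance = 1e-12)

  expect_warning(res2 <- mann_whitney(rep(2, 5), rep(2, 4)), "identical")
  expect_equal(res2$p_raw, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact and approximate Mann-Whitney branches agree at n = 8", {
  # the continuity-corrected normal approximation tracks the exact
  # enumeration to ~0.01 in p at n = 8 (worst case just over; the
  # uncorrected approximation is ~4x worse)
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- mann_whitney(x, y, exact_max = 8)$p_raw
    p_approx <- mann_whitney(x, y, exact_max = 0)$p_raw
    expect_lt(abs(p_exact - p_approx), 0.011)
  }
})

test_that("default-cohort rCBV group difference is detected across seeds", {
  hits <- 0
  for (r in 1:100) {
    co <- ground_truth_profiles(
      generate_cohort_table(cohort_config(seed = 2000 + r)))
    hi <- co$phenotype == "high"
    p <- mann_whitney(co$median_rcbv[hi], co$median_rcbv[!hi])$p_raw
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.9)
})

test_that("Fisher's exact test reproduces the printed location p-values", {
  # frontal: 7/37 high vs 22/50 low
  frontal <- fisher_exact(matrix(c(7, 30, 22, 28), 2, byrow = TRUE),
                          label = "frontal")
  expect_lt(abs(frontal$p_raw - 0.0209), 5e-5)
  expect_equal(frontal$odds_ratio, (7 * 28) / (30 * 22))

  # temporal: 13/37 high vs 8/50 low
  temporal <- fisher_exact(matrix(c(13, 24, 8, 42), 2, byrow = TRUE))
  expect_lt(abs(temporal$p_raw - 0.0464), 5e-5)

  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_raw, 1)
  expect_warning(z <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "margin")
  expect_equal(z$p_raw, 1)
})

test_that("Fisher's test is invariant to simultaneous row and column swaps", {
  set.seed(62)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 10), 2)
    p1 <- fisher_exact(tab)$p_raw
    p2 <- fisher_exact(tab[2:1, 2:1])$p_raw
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("BH step-up adjustment matches hand-computed values", {
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)  # single test unchanged

  # the five location tests: smallest adjusted = 0.0209 * 5 / 1 = 0.1045
  res <- bh_adjust(c(0.0209, 0.0464, 0.30, 0.50, 0.70))
  expect_equal(min(res$p_adj), 0.1045, tolerance = 1e-10)
  expect_equal(sum(res$reject), 0)

  res2 <- bh_adjust(rep(0.01, 5))
  expect_equal(res2$p_adj, rep(0.01, 5))
  expect_true(all(res2$reject))
})

test_that("BH never rejects more than the unadjusted rule and is monotone", {
  set.seed(63)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    res <- bh_adjust(p)
    expect_lte(sum(res$reject), sum(p <= 0.05))
    expect_true(all(res$p_adj >= p - 1e-12))
    # adjusted values preserve the ordering of the raw values
    expect_true(all(diff(res$p_adj[order(p)]) >= -1e-12))
  }
})

test_that("qT2-adjusted regression recovers exact coefficients", {
  qt2 <- seq(80, 140, length.out = 40)
  grp <- rep(c("high", "low"), 20)
  mtr <- 1.0 + 0.6 * (grp == "high") + 0.01 * qt2
  res <- adjusted_group_regression(mtr, grp, qt2)
  expect_equal(res$summary$beta_group, 0.6, tolerance = 1e-10)
  expect_equal(res$summary$r2, 1, tolerance = 1e-10)
  expect_equal(unname(tidy(res)$estimate[tidy(res)$term == "qt2"]), 0.01,
               tolerance = 1e-10)

  # permuted phenotype: null behavior
  set.seed(64)
  n <- 1000
  qt2n <- rnorm(n, 105, 12)
  mtrn <- 2 + 0.01 * qt2n + rnorm(n, 0, 0.4)
  grpn <- sample(rep(c("high", "low"), n / 2))
  resn <- adjusted_group_regression(mtrn, grpn, qt2n)
  expect_lt(abs(resn$summary$beta_group), 0.1)

  mtr_flat <- 1.0 + 0.6 * (grp == "high") + 0.01 * 100
  expect_warning(
    resz <- adjusted_group_regression(mtr_flat, grp, rep(100, 40)),
    "zero-variance")
  expect_equal(resz$summary$beta_group, 0.6, tolerance = 1e-10)
  expect_error(adjusted_group_regression(mtr[1:2], grp[1:2], qt2[1:2]),
               "complete cases")
})

test_that("Pearson matrix handles exact, null and degenerate cases", {
  x <- 1:50
  pm <- pearson_matrix(data.frame(x = x, y = 2 * x, z = -x + 100))
  expect_equal(pm$r["x", "y"], 1)
  expect_equal(pm$r["x", "z"], -1)
  expect_equal(diag(pm$r), c(x = 1, y = 1, z = 1))

  set.seed(65)
  ind <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(pearson_matrix(ind)$r["a", "b"]), 0.1)

  expect_warning(pz <- pearson_matrix(data.frame(a = rnorm(10),
                                                 c = rep(1, 10))),
                 "degenerate")
  expect_true(is.na(pz$r["a", "c"]))

  td <- tidy(pm)
  expect_equal(nrow(td), 3)  # three unordered pairs
})

test_that("k-means phenotype clustering separates clean groups deterministically", {
  set.seed(66)
  df <- tibble::tibble(
    lesion_id = sprintf("L%02d", 1:40),
    adc_l = c(rnorm(20, 1500, 80), rnorm(20, 1000, 80)),
    median_rcbv = c(rnorm(20, 1.0, 0.1), rnorm(20, 1.3, 0.1)),
    median_mtr_asym = c(rnorm(20, 2.4, 0.2), rnorm(20, 2.1, 0.2)))
  cl <- kmeans_phenotype_cluster(df, seed = 9)
  expect_equal(cl$concordance, 1)
  expect_equal(cl$n_discordant, 0)
  # cluster 1 is the high-ADC_L cluster by the relabeling rule
  expect_true(all(cl$assignments$cluster[1:20] == 1))

  cl2 <- kmeans_phenotype_cluster(df, seed = 9)
  expect_identical(cl$assignments, cl2$assignments)

  expect_error(kmeans_phenotype_cluster(df[c(1, 1), ]), "distinct")
})

test_that("Shapiro gate flags non-normal samples and logs degenerate input", {
  set.seed(67)
  expect_false(shapiro_gate(runif(500))$normal)
  ok <- 0
  for (i in 1:20) ok <- ok + shapiro_gate(rnorm(500))$normal
  expect_gte(ok, 18)
  expect_warning(g <- shapiro_gate(c(1, 2)), "fewer than 3")
  expect_true(is.na(g$normal))
  expect_warning(g2 <- shapiro_gate(rep(5, 10)), "constant")
  expect_true(is.na(g2$normal))
})
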