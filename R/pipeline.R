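#' Process one lesion bundle into a lesion profile
#'
#' Runs the full per-lesion quantification: ADC from the DWI pair, deltaT1
#' from the normalized T1w subtraction, leakage-corrected brain-median-
#' normalized rCBV from the DSC series, B0-corrected MTR_asym at 3 ppm from
#' the z-spectra (with the per-lesion field-inhomogeneity quality gate), and
#' SAGE qT2/qT2* when echoes are present; then extracts the LesionProfile
#' row (double-Gaussian ADC_L, phenotype, ROI medians, CE volume, RANO flag).
#'
#' @param bundle A [simulate_lesion()] bundle (or one read from disk with
#'   [read_lesion_bundle()]).
#' @param cutoff ADC_L cutoff in um^2/s.
#' @param n_clusters_b0 Cluster count for the B0 estimation.
#' @param b0_threshold Voxel flagging threshold in ppm.
#' @param max_flagged_frac Lesion-level CEST exclusion fraction.
#' @param cest_seed Seed for the z-spectrum clustering (defaults to a value
#'   derived from the bundle's simulation seed for reproducibility).
#' @param keep_maps Also return the computed maps.
#' @return One-row tibble (LesionProfile); with `keep_maps = TRUE`, a list
#'   `(profile, maps)`.
#' @export
process_lesion <- function(bundle, cutoff = 1240, n_clusters_b0 = 4,
                           b0_threshold = 0.3, max_flagged_frac = 0.25,
                           cest_seed = NULL, keep_maps = FALSE) {
  stopifnot(inherits(bundle, "lesion_bundle"))
  tumor <- bundle$tumor
  brain <- bundle$brain
  if (is.null(cest_seed)) {
    cest_seed <- derive_seed(bundle$truth$sim_seed %||% 1, 101)
  }

  adc <- compute_adc(bundle$dwi)
  dt1 <- compute_delta_t1(delta_t1_inputs(bundle$t1w_pre, bundle$t1w_post,
                                          brain))
  rcbv <- compute_rcbv(bundle$dsc, brain, deltat1 = dt1, tumor = tumor)

  clusters <- cluster_zspectra(bundle$zspectra, brain,
                               n_clusters = n_clusters_b0, seed = cest_seed)
  b0 <- estimate_b0(clusters, threshold = b0_threshold)
  corrected <- correct_b0(bundle$zspectra, b0)
  mtr <- compute_mtr_asym(corrected)
  cest_ok <- cest_lesion_valid(b0, tumor, max_flagged_frac)

  maps <- list(adc = adc, rcbv = rcbv, mtr_asym = mtr, deltat1 = dt1)
  if (!is.null(bundle$sage)) {
    relax <- solve_sage(bundle$sage)
    maps$qt2 <- relax$qt2
    maps$qt2star <- relax$qt2star
  }

  clinical <- NULL
  if (!is.null(bundle$truth)) {
    keep <- intersect(c("lesion_id", "location", "sex", "mgmt", "egfr",
                        "steroid_dose_mg", "age"), names(bundle$truth))
    clinical <- bundle$truth[keep]
  }
  profile <- extract_lesion_profile(maps, tumor, clinical = clinical,
                                    cutoff = cutoff)
  profile$cest_valid <- cest_ok
  if (!cest_ok) profile$median_mtr_asym <- NA_real_
  if (keep_maps) list(profile = profile, maps = maps) else profile
}

#' Run the full pipeline over a synthetic cohort
#'
#' Streams through the cohort: simulates each lesion's raw bundle, processes
#' it with [process_lesion()], and assembles the cohort table. Per-lesion
#' failures are isolated: the lesion is excluded with a logged reason rather
#' than aborting the run.
#'
#' @param config A [cohort_config()], or a [generate_cohort()] object.
#' @param progress Print one line per lesion.
#' @return Object of class `cohort_run`: `cohort` (lesion-profile tibble),
#'   `ground_truth`, `exclusions` (tibble of lesion_id + reason), `config`.
#' @export
run_synthetic_cohort <- function(config, progress = FALSE) {
  cohort <- if (inherits(config, "synthetic_cohort")) config else
    generate_cohort(config)
  truth <- cohort$ground_truth
  profiles <- vector("list", nrow(truth))
  excl <- list()
  for (i in seq_len(nrow(truth))) {
    res <- tryCatch({
      b <- cohort$bundle(i)
      process_lesion(b, cutoff = cohort$config$cutoff,
                     n_clusters_b0 = cohort$config$n_clusters_b0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        lesion_id = truth$lesion_id[i], reason = conditionMessage(res))
      if (progress) message(truth$lesion_id[i], " EXCLUDED: ",
                            conditionMessage(res))
    } else {
      profiles[[i]] <- res
      if (progress) message(truth$lesion_id[i], " done (",
                            res$phenotype, ", ADC_L ", round(res$adc_l), ")")
    }
  }
  structure(list(cohort = dplyr::bind_rows(profiles),
                 ground_truth = truth,
                 exclusions = if (length(excl)) dplyr::bind_rows(excl) else
                   tibble::tibble(lesion_id = character(),
                                  reason = character()),
                 config = cohort$config),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat("<cohort_run> ", nrow(x$cohort), " lesions profiled (",
      sum(x$cohort$phenotype == "high"), " high / ",
      sum(x$cohort$phenotype == "low"), " low), ",
      nrow(x$exclusions), " excluded\n", sep = "")
  invisible(x)
}

# One-vs-rest 2x2 location table: rows location yes/no, columns high/low.
location_table <- function(cohort, level) {
  hi <- cohort$phenotype == "high"
  matrix(c(sum(cohort$location == level & hi),
           sum(cohort$location == level & !hi),
           sum(cohort$location != level & hi),
           sum(cohort$location != level & !hi)),
         2, 2, byrow = TRUE)
}

two_level_table <- function(cohort, col, levels) {
  keep <- cohort[[col]] %in% levels
  hi <- cohort$phenotype[keep] == "high"
  v <- cohort[[col]][keep]
  matrix(c(sum(v == levels[1] & hi), sum(v == levels[1] & !hi),
           sum(v == levels[2] & hi), sum(v == levels[2] & !hi)),
         2, 2, byrow = TRUE)
}

#' Cohort-level statistical analysis
#'
#' The full group-comparison battery on a lesion-profile table:
#' Mann-Whitney U tests of the six MRI metrics (CE volume, median deltaT1,
#' median rCBV, median MTR_asym, median qT2, median qT2*) between diffusion
#' phenotypes with Benjamini-Hochberg correction as one family; a
#' Mann-Whitney test of corticosteroid dose; Fisher's exact tests of the five
#' lesion locations (one-vs-rest, BH family of 5) and of sex, MGMT and EGFR
#' (unknowns excluded); the qT2-adjusted linear regression of MTR_asym on
#' phenotype; Pearson correlations among the MRI metrics; k-means phenotype
#' clustering (k = 2) on ADC_L, median rCBV and median MTR_asym; and
#' Shapiro-Wilk normality logging per metric and group (the battery always
#' proceeds nonparametrically).
#'
#' Missing values are handled per-analysis by complete cases, never imputed.
#'
#' @param cohort Lesion-profile tibble (from [run_synthetic_cohort()]'s
#'   `$cohort`, [ground_truth_profiles()], or a CSV of the same shape).
#' @param alpha Significance level / FDR target.
#' @param seed Seed for the k-means clustering.
#' @param cutoff ADC_L cutoff in um^2/s.
#' @return Object of class `cohort_report` with elements `comparisons`,
#'   `location_tests`, `clinical_tests`, `regression`, `correlations`,
#'   `clusters`, `normality`, `n_lesions`, `alpha`.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, seed = 42, cutoff = 1240) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("adc_l", "phenotype") %in% names(cohort)))
  hi <- cohort$phenotype == "high"
  metrics <- c("volume_cc", "median_deltat1", "median_rcbv",
               "median_mtr_asym", "median_qt2", "median_qt2star")
  metrics <- intersect(metrics, names(cohort))
  comparisons <- dplyr::bind_rows(lapply(metrics, function(m) {
    mann_whitney(cohort[[m]][hi], cohort[[m]][!hi], metric = m,
                 family = "mri_metrics")
  }))
  adj <- bh_adjust(comparisons$p_raw, alpha)
  comparisons$p_adj <- adj$p_adj
  comparisons$reject <- adj$reject
  if ("steroid_dose_mg" %in% names(cohort)) {
    ster <- mann_whitney(cohort$steroid_dose_mg[hi],
                         cohort$steroid_dose_mg[!hi],
                         metric = "steroid_dose_mg", family = "clinical")
    ster$p_adj <- ster$p_raw
    ster$reject <- ster$p_raw <= alpha
    comparisons <- dplyr::bind_rows(comparisons, ster)
  }

  location_tests <- NULL
  if ("location" %in% names(cohort)) {
    levs <- sort(unique(cohort$location))
    location_tests <- dplyr::bind_rows(lapply(levs, function(l) {
      fisher_exact(location_table(cohort, l), label = l,
                   family = "location")
    }))
    adj <- bh_adjust(location_tests$p_raw, alpha)
    location_tests$p_adj <- adj$p_adj
    location_tests$reject <- adj$reject
  }

  clinical_tests <- NULL
  cl_specs <- list(sex = c("male", "female"),
                   mgmt = c("methylated", "unmethylated"),
                   egfr = c("amplified", "non_amplified"))
  cl_specs <- cl_specs[names(cl_specs) %in% names(cohort)]
  if (length(cl_specs)) {
    clinical_tests <- dplyr::bind_rows(purrr::imap(cl_specs, function(lv, nm) {
      fisher_exact(two_level_table(cohort, nm, lv), label = nm,
                   family = "clinical")
    }))
    adj <- bh_adjust(clinical_tests$p_raw, alpha)
    clinical_tests$p_adj <- adj$p_adj
    clinical_tests$reject <- adj$reject
  }

  regression <- NULL
  if (all(c("median_mtr_asym", "median_qt2") %in% names(cohort))) {
    regression <- tryCatch(
      adjusted_group_regression(cohort$median_mtr_asym, cohort$phenotype,
                                cohort$median_qt2),
      error = function(e) {
        vlog("analyze_cohort: regression skipped (", conditionMessage(e), ")")
        NULL
      })
  }

  cor_cols <- intersect(c("adc_l", "median_qt2", "median_qt2star",
                          "median_mtr_asym"), names(cohort))
  correlations <- if (length(cor_cols) >= 2) {
    pearson_matrix(cohort[cor_cols])
  } else NULL

  clusters <- tryCatch(
    kmeans_phenotype_cluster(cohort, seed = seed, cutoff = cutoff),
    error = function(e) {
      vlog("analyze_cohort: clustering skipped (", conditionMessage(e), ")")
      NULL
    })

  normality <- dplyr::bind_rows(lapply(metrics, function(m) {
    dplyr::bind_rows(lapply(c(TRUE, FALSE), function(h) {
      g <- suppressWarnings(shapiro_gate(cohort[[m]][hi == h], alpha))
      g$metric <- m
      g$group <- if (h) "high" else "low"
      g
    }))
  }))

  structure(list(comparisons = comparisons, location_tests = location_tests,
                 clinical_tests = clinical_tests, regression = regression,
                 correlations = correlations, clusters = clusters,
                 normality = normality, n_lesions = nrow(cohort),
                 alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", x$n_lesions, " lesions\n\nGroup comparisons:\n",
      sep = "")
  print(x$comparisons)
  if (!is.null(x$location_tests)) {
    cat("\nLocation tests (Fisher, BH family of ",
        nrow(x$location_tests), "):\n", sep = "")
    print(x$location_tests)
  }
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression)
  }
  if (!is.null(x$clusters)) {
    cat("\n")
    print(x$clusters)
  }
  invisible(x)
}

# ---- disk I/O driver ------------------------------------------------------

#' Read a lesion bundle from disk
#'
#' Reads the NIfTI volumes and JSON sidecars written by [generate_cohort()]
#' (`tumor`, `brain`, `dwi_b0`/`dwi_b1000`, `t1w_pre`/`t1w_post`, `dsc` +
#' `dsc.json`, `cest` + `cest_s0` + `cest.json`, optional `sage` +
#' `sage.json`).
#'
#' @param path Lesion directory.
#' @param truth Optional ground-truth row to attach.
#' @return A `lesion_bundle`.
#' @export
read_lesion_bundle <- function(path, truth = NULL) {
  rd <- function(f) read_volume(file.path(path, f))
  rd4 <- function(f) as.array(RNifti::readNifti(file.path(path, f)))
  tumor_v <- rd("tumor.nii.gz")
  tumor <- binary_mask(tumor_v$data > 0.5, tumor_v$spacing, "tumor_ce")
  brain_v <- rd("brain.nii.gz")
  brain <- binary_mask(brain_v$data > 0.5, brain_v$spacing, "brain")
  sp <- tumor_v$spacing
  dwi <- dwi_pair(rd("dwi_b0.nii.gz"), rd("dwi_b1000.nii.gz"))
  dmeta <- jsonlite::read_json(file.path(path, "dsc.json"),
                               simplifyVector = TRUE)
  dsc <- dsc_series(rd4("dsc.nii.gz"), tr = dmeta$tr, te = dmeta$te,
                    baseline_idx = dmeta$baseline_idx, spacing = sp)
  cmeta <- jsonlite::read_json(file.path(path, "cest.json"),
                               simplifyVector = TRUE)
  zspectra <- zspectrum_series(rd4("cest.nii.gz"), cmeta$offsets_ppm,
                               rd("cest_s0.nii.gz"), spacing = sp)
  sage <- NULL
  if (file.exists(file.path(path, "sage.nii.gz"))) {
    smeta <- jsonlite::read_json(file.path(path, "sage.json"),
                                 simplifyVector = TRUE)
    arr <- rd4("sage.nii.gz")
    sage <- sage_echo_set(matrix(arr, prod(dim(arr)[1:3]), 4),
                          smeta$te_ms, smeta$te_se_ms,
                          dim3 = dim(arr)[1:3], spacing = sp)
  }
  structure(list(tumor = tumor, brain = brain, dwi = dwi, dsc = dsc,
                 zspectra = zspectra, sage = sage,
                 t1w_pre = rd("t1w_pre.nii.gz"),
                 t1w_post = rd("t1w_post.nii.gz"), truth = truth),
            class = "lesion_bundle")
}

#' Run the pipeline from a configuration
#'
#' Single entry point wiring simulate -> maps -> phenotype -> stats. The
#' configuration may be a [cohort_config()], a YAML file of overrides for
#' it, or a list of overrides. With `manifest`, bundles are read from disk
#' (one row per lesion: `lesion_id`, `path`) instead of simulated; per-lesion
#' failures become logged exclusions, not global aborts. Results are
#' optionally written as `cohort.csv` and `report.json`.
#'
#' @param config A [cohort_config()], a YAML path, or a list of overrides.
#' @param manifest Optional manifest CSV path or data frame.
#' @param out_dir Optional output directory.
#' @param progress Verbose per-lesion logging.
#' @return List of class `pipeline_result`: `cohort`, `report`,
#'   `exclusions`, `config`.
#' @export
run_pipeline <- function(config = cohort_config(), manifest = NULL,
                         out_dir = NULL, progress = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  if (is.null(manifest)) {
    run <- run_synthetic_cohort(config, progress = progress)
    cohort <- run$cohort
    exclusions <- run$exclusions
  } else {
    if (is.character(manifest)) {
      manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    }
    truth_path <- file.path(dirname(manifest$path[1]), "ground_truth.csv")
    truth <- if (file.exists(truth_path)) {
      tibble::as_tibble(utils::read.csv(truth_path,
                                        stringsAsFactors = FALSE))
    } else NULL
    profiles <- list()
    excl <- list()
    for (i in seq_len(nrow(manifest))) {
      res <- tryCatch({
        trow <- if (!is.null(truth)) {
          truth[truth$lesion_id == manifest$lesion_id[i], ]
        } else NULL
        b <- read_lesion_bundle(manifest$path[i],
                                truth = if (!is.null(trow) && nrow(trow))
                                  trow else NULL)
        process_lesion(b, cutoff = config$cutoff,
                       n_clusters_b0 = config$n_clusters_b0,
                       cest_seed = derive_seed(config$seed, i))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          lesion_id = as.character(manifest$lesion_id[i]),
          reason = conditionMessage(res))
      } else {
        if (!"lesion_id" %in% names(res)) {
          res$lesion_id <- as.character(manifest$lesion_id[i])
        }
        profiles[[length(profiles) + 1]] <- res
      }
    }
    cohort <- dplyr::bind_rows(profiles)
    exclusions <- if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(lesion_id = character(), reason = character())
  }
  report <- analyze_cohort(cohort, seed = config$seed,
                           cutoff = config$cutoff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cohort = cohort, report = report, exclusions = exclusions,
                 config = config),
            class = "pipeline_result")
}

# Serializable view of a cohort report.
report_to_list <- function(report) {
  list(
    n_lesions = report$n_lesions,
    alpha = report$alpha,
    comparisons = report$comparisons,
    location_tests = report$location_tests,
    clinical_tests = report$clinical_tests,
    regression = if (!is.null(report$regression))
      report$regression$summary else NULL,
    correlations = if (!is.null(report$correlations)) list(
      r = as.data.frame(report$correlations$r),
      p = as.data.frame(report$correlations$p)) else NULL,
    clusters = if (!is.null(report$clusters)) list(
      concordance = report$clusters$concordance,
      n_discordant = report$clusters$n_discordant,
      seed = report$clusters$seed,
      assignments = report$clusters$assignments) else NULL,
    normality = report$normality)
}
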