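#' SAGE-EPI multi-echo reference set
#'
#' Four echoes of a spin-and-gradient-echo EPI acquisition, ordered by echo
#' time: two gradient echoes, one mixed echo and one spin echo. The last echo
#' time must equal the spin-echo time.
#'
#' @param echoes List of 4 [image_volume()]s, or a voxel-by-4 matrix for a
#'   masked representation (then give `voxels`, `dim3`, `spacing`).
#' @param te_ms Echo times in ms, strictly increasing.
#' @param te_se_ms Spin-echo time in ms; must equal `te_ms[4]`.
#' @param voxels,dim3,spacing,frame_id Masked-representation metadata.
#' @return An object of class `sage_echo_set` with `regime =
#'   c("gradient", "gradient", "spin", "spin")`.
#' @export
sage_echo_set <- function(echoes, te_ms, te_se_ms = te_ms[4], voxels = NULL,
                          dim3 = NULL, spacing = c(1, 1, 1),
                          frame_id = "common") {
  if (length(te_ms) != 4L || any(diff(te_ms) <= 0)) {
    stop("sage_echo_set: te_ms must be 4 strictly increasing echo times")
  }
  if (abs(te_ms[4] - te_se_ms) > 1e-9) {
    stop("sage_echo_set: the last echo time must equal the spin-echo time")
  }
  if (is.list(echoes)) {
    if (length(echoes) != 4L) stop("sage_echo_set: need 4 echo volumes")
    for (i in 2:4) assert_same_grid(echoes[[1]], echoes[[i]], "echo volumes")
    mat <- vapply(echoes, function(v) as.numeric(v$data),
                  numeric(length(echoes[[1]]$data)))
    dim3 <- dim(echoes[[1]]$data)
    spacing <- echoes[[1]]$spacing
    frame_id <- echoes[[1]]$frame_id
    voxels <- NULL
  } else {
    mat <- as.matrix(echoes)
    if (ncol(mat) != 4L) stop("sage_echo_set: matrix must have 4 columns")
    if (is.null(dim3)) stop("sage_echo_set: masked form needs dim3")
  }
  structure(list(signal = mat, te_ms = as.numeric(te_ms),
                 te_se_ms = te_se_ms,
                 regime = c("gradient", "gradient", "spin", "spin"),
                 voxels = voxels, dim3 = as.integer(dim3),
                 spacing = as.numeric(spacing), frame_id = frame_id),
            class = "sage_echo_set")
}

# Piecewise SAGE signal model (tau and TE_SE in seconds):
#   gradient regime: S(tau) = S0_I  * exp(-tau * R2*)
#   spin regime:     S(tau) = S0_II * exp(-TE_SE * (R2* - R2))
#                                   * exp(-tau * (2 R2 - R2*))
# At tau = TE_SE the spin-regime model reduces to S0_II * exp(-TE_SE * R2).
sage_forward <- function(s0_i, s0_ii, r2, r2star, te_ms, te_se_ms) {
  tau <- te_ms / 1000
  tse <- te_se_ms / 1000
  cbind(
    s0_i * exp(-tau[1] * r2star),
    s0_i * exp(-tau[2] * r2star),
    s0_ii * exp(-tse * (r2star - r2)) * exp(-tau[3] * (2 * r2 - r2star)),
    s0_ii * exp(-tse * (r2star - r2)) * exp(-tau[4] * (2 * r2 - r2star)))
}

#' Quantitative T2 and T2* maps from SAGE echoes
#'
#' Closed-form solution of the piecewise gradient/spin-echo signal equations:
#' `R2* = ln(S1/S2) / (tau2 - tau1)` from the gradient pair,
#' `2 R2 - R2* = ln(S3/S4) / (tau4 - tau3)` from the spin pair, hence
#' `R2 = (ln(S3/S4)/(tau4 - tau3) + R2*) / 2`, with `qT2 = 1000/R2` ms and
#' `qT2* = 1000/R2*` ms. Four unknowns and four echoes make the system
#' exactly determined, so the closed form is the least-squares solution; an
#' optional per-voxel nonlinear refinement (`refine = TRUE`) is provided and
#' can never increase the residual sum of squares. Voxels with non-positive
#' signals or non-positive rates are marked invalid (NaN).
#'
#' @param echoes A [sage_echo_set()].
#' @param refine Run a per-voxel nonlinear least-squares polish (slow; only
#'   sensible for small ROIs).
#' @return List with `qt2` and `qt2star` [image_volume()]s (ms) and a `valid`
#'   [binary_mask()]-style logical volume attached as attribute on each map.
#' @export
solve_sage <- function(echoes, refine = FALSE) {
  stopifnot(inherits(echoes, "sage_echo_set"))
  S <- echoes$signal
  tau <- echoes$te_ms / 1000
  pos <- rowSums(S <= 0 | !is.finite(S)) == 0
  r2star <- rep(NA_real_, nrow(S))
  a <- rep(NA_real_, nrow(S))
  r2star[pos] <- log(S[pos, 1] / S[pos, 2]) / (tau[2] - tau[1])
  a[pos] <- log(S[pos, 3] / S[pos, 4]) / (tau[4] - tau[3])
  r2 <- (a + r2star) / 2
  if (isTRUE(refine)) {
    ref <- sage_refine(S, r2, r2star, echoes$te_ms, echoes$te_se_ms)
    r2 <- ref$r2
    r2star <- ref$r2star
  }
  qt2 <- ifelse(is.finite(r2) & r2 > 0, 1000 / r2, NA_real_)
  qt2star <- ifelse(is.finite(r2star) & r2star > 0, 1000 / r2star, NA_real_)
  dim3 <- echoes$dim3
  list(
    qt2 = values_to_volume(qt2, echoes$voxels, dim3, echoes$spacing,
                           echoes$frame_id),
    qt2star = values_to_volume(qt2star, echoes$voxels, dim3, echoes$spacing,
                               echoes$frame_id))
}

# Per-voxel joint NLS over the 4 echoes, warm-started at the closed form.
# Exactly determined, so it can only tie or reduce rss (guarded explicitly).
sage_refine <- function(S, r2, r2star, te_ms, te_se_ms) {
  for (i in which(is.finite(r2) & is.finite(r2star))) {
    y <- S[i, ]
    s0_i0 <- y[1] * exp(te_ms[1] / 1000 * r2star[i])
    s0_ii0 <- y[4] * exp(te_se_ms / 1000 * r2[i])
    start <- c(s0_i = s0_i0, s0_ii = s0_ii0, r2 = r2[i], r2star = r2star[i])
    rss0 <- sum((sage_forward(s0_i0, s0_ii0, r2[i], r2star[i], te_ms,
                              te_se_ms) - y)^2)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) {
          as.numeric(sage_forward(p[1], p[2], p[3], p[4], te_ms,
                                  te_se_ms)) - y
        }),
      error = function(e) NULL)
    if (!is.null(fit) && sum(fit$fvec^2) <= rss0) {
      r2[i] <- fit$par[3]
      r2star[i] <- fit$par[4]
    }
  }
  list(r2 = r2, r2star = r2star)
}

#' ROI medians of the relaxation maps
#'
#' @param qt2,qt2star [image_volume()]s from [solve_sage()].
#' @param mask Tumor [binary_mask()].
#' @return One-row tibble with `median_qt2`, `median_qt2star` (ms) and the
#'   valid-voxel counts; medians are `NA` when no valid voxel exists (the
#'   lesion is then missing for relaxometry).
#' @export
roi_qt2_medians <- function(qt2, qt2star, mask) {
  v2 <- suppressWarnings(masked_values(qt2, mask))
  v2s <- suppressWarnings(masked_values(qt2star, mask))
  if (length(v2) == 0) vlog("roi_qt2_medians: no valid qT2 voxels in ROI")
  tibble::tibble(
    median_qt2 = if (length(v2)) stats::median(v2) else NA_real_,
    median_qt2star = if (length(v2s)) stats::median(v2s) else NA_real_,
    n_valid_qt2 = length(v2), n_valid_qt2star = length(v2s))
}
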