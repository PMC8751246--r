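#' Describe a block correlation structure
#'
#' A predictor set is modelled as `n_clinical` weakly correlated "clinical"
#' predictors followed by one or more exchangeable blocks of organ-at-risk
#' dose predictors. Within a dose block the pairwise correlation is
#' `within_block_r`, across dose blocks it is `between_block_r`, and the
#' clinical predictors correlate at a fixed 0.1 with everything (and with each
#' other).
#'
#' @param block_sizes integer vector of dose-block sizes (each >= 1).
#' @param within_block_r correlation inside each dose block, in `[0, 1)`.
#'   Recycled to `length(block_sizes)`.
#' @param between_block_r correlation between predictors of different dose
#'   blocks, in `[0, 1)`.
#' @param n_clinical number of clinical predictors (>= 0).
#' @return an object of class `block_structure`.
#' @export
#' @examples
#' bs <- block_structure(c(2, 2), within_block_r = 0.9, between_block_r = 0.3,
#'                       n_clinical = 3)
#' R <- build_block_correlation(bs)
#' population_median_vif(R)
block_structure <- function(block_sizes, within_block_r, between_block_r = 0,
                            n_clinical = 0) {
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1 || any(block_sizes < 1))
    stopf("block_sizes must be positive integers")
  within_block_r <- rep_len(within_block_r, length(block_sizes))
  if (any(within_block_r < 0) || any(within_block_r >= 1))
    stopf("within_block_r must lie in [0, 1)")
  if (between_block_r < 0 || between_block_r >= 1)
    stopf("between_block_r must lie in [0, 1)")
  if (n_clinical < 0) stopf("n_clinical must be >= 0")
  structure(list(block_sizes = block_sizes,
                 within_block_r = within_block_r,
                 between_block_r = between_block_r,
                 n_clinical = as.integer(n_clinical),
                 p = sum(block_sizes) + as.integer(n_clinical)),
            class = "block_structure")
}

# weak background correlation among clinical predictors and between
# clinical and dose predictors
CLINICAL_R <- 0.1

#' @keywords internal
block_pattern_matrix <- function(bs, within_r) {
  p <- bs$p
  nc <- bs$n_clinical
  R <- matrix(CLINICAL_R, p, p)
  offset <- nc
  dose_idx <- if (p > nc) (nc + 1L):p else integer(0)
  if (length(dose_idx))
    R[dose_idx, dose_idx] <- bs$between_block_r
  for (k in seq_along(bs$block_sizes)) {
    idx <- offset + seq_len(bs$block_sizes[k])
    R[idx, idx] <- within_r[k]
    offset <- offset + bs$block_sizes[k]
  }
  diag(R) <- 1
  R
}

#' Build the exchangeable block correlation matrix
#'
#' Constructs the correlation matrix implied by a [block_structure()]: the
#' given within-block correlation inside each dose block, `between_block_r`
#' across dose blocks, and a fixed weak 0.1 correlation among clinical
#' predictors and between clinical and dose predictors. The result is repaired
#' to positive definiteness if necessary (eigenvalue floor, re-normalized to a
#' unit diagonal).
#'
#' @param bs a [block_structure()].
#' @return a `correlation_structure`: a list with elements `matrix` (p x p) and
#'   `provenance` (free text describing the construction).
#' @export
build_block_correlation <- function(bs) {
  stopifnot(inherits(bs, "block_structure"))
  R <- block_pattern_matrix(bs, bs$within_block_r)
  R <- repair_pd(R)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    stopf(paste0("correlation matrix not positive definite after repair ",
                 "(blocks: %s; within r: %s; between r: %.3f)"),
          paste(bs$block_sizes, collapse = ","),
          paste(signif(bs$within_block_r, 3), collapse = ","),
          bs$between_block_r)
  correlation_structure(R, sprintf(
    "exchangeable block correlation: %d clinical (r=%.2f), blocks [%s], within r [%s], between r %.2f",
    bs$n_clinical, CLINICAL_R, paste(bs$block_sizes, collapse = ","),
    paste(signif(bs$within_block_r, 3), collapse = ","), bs$between_block_r))
}

#' @keywords internal
correlation_structure <- function(R, provenance = "") {
  if (max(abs(R - t(R))) > 1e-12) stopf("correlation matrix not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-12) stopf("correlation matrix diagonal not 1")
  structure(list(matrix = R, provenance = provenance),
            class = "correlation_structure")
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Floors the eigenvalues at `floor_ev`, reconstructs, and re-normalizes the
#' diagonal to 1. Deterministic; a no-op for matrices already PD.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor_ev eigenvalue floor.
#' @return repaired matrix.
#' @export
repair_pd <- function(R, floor_ev = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor_ev) return((R + t(R)) / 2)
  ev <- pmax(e$values, floor_ev)
  R2 <- e$vectors %*% (ev * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

#' Population median variance inflation factor
#'
#' For standardized multivariate-normal predictors with correlation matrix R,
#' the VIF of predictor j is the j-th diagonal entry of the inverse of R; this
#' returns the median over predictors. A value of 1 indicates absence of
#' collinearity.
#'
#' @param corr a `correlation_structure` or plain correlation matrix.
#' @return positive scalar, the median VIF.
#' @export
population_median_vif <- function(corr) {
  R <- if (inherits(corr, "correlation_structure")) corr$matrix else corr
  Ri <- tryCatch(chol2inv(chol(R)),
                 error = function(e) stopf("correlation matrix is singular"))
  stats::median(diag(Ri))
}

#' Sample variance inflation factors
#'
#' VIF per column of a data matrix: `1 / (1 - R^2_j)`, where `R^2_j` comes
#' from the OLS regression of column j on all other columns plus an intercept.
#' Perfect linear dependence is reported as `Inf` with a warning rather than
#' an error.
#'
#' @param X numeric matrix, `n > p + 1`, no constant columns.
#' @return length-p vector of VIFs (possibly `Inf`).
#' @export
sample_vif <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stopf("sample_vif needs n > p + 1 (got n=%d, p=%d)", n, p)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  tss <- colSums(Xc^2)
  if (any(tss == 0)) stopf("constant column(s): %s",
                           paste(which(tss == 0), collapse = ","))
  vif <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::.lm.fit(Xc[, -j, drop = FALSE], Xc[, j])
    r2 <- 1 - sum(fit$residuals^2) / tss[j]
    if (r2 >= 1 - 1e-12) {
      vif[j] <- Inf
    } else {
      vif[j] <- 1 / (1 - r2)
    }
  }
  if (any(is.infinite(vif)))
    warnf("perfect linear dependence: VIF reported as Inf for column(s) %s",
          paste(which(is.infinite(vif)), collapse = ","))
  vif
}

#' Calibrate a correlation matrix to a target median VIF
#'
#' Moves the base matrix along a one-parameter convex path and bisects on the
#' mixing weight until the population median VIF matches the target within a
#' 1\% relative tolerance. De-correlation mixes towards the identity,
#' `R(a) = (1-a) R + a I`; amplification mixes towards a saturated version of
#' the same block pattern with within-block correlation 0.995. Positive-
#' definiteness is repaired after every step.
#'
#' @param corr base `correlation_structure`.
#' @param target_median_vif target, >= 1.
#' @param bs the [block_structure()] that generated `corr`; required only for
#'   amplification (targets above the base VIF).
#' @param rel_tol relative tolerance of the calibration (default 0.01).
#' @return calibrated `correlation_structure` with attributes `alpha`
#'   (mixing weight used) and `path` ("none", "decorrelate" or "saturate").
#' @export
calibrate_collinearity <- function(corr, target_median_vif, bs = NULL,
                                   rel_tol = 0.01) {
  stopifnot(inherits(corr, "correlation_structure"))
  if (target_median_vif < 1)
    stopf("target median VIF must be >= 1 (got %g): attainable range is [1, Inf)",
          target_median_vif)
  R0 <- corr$matrix
  v0 <- population_median_vif(R0)

  done <- function(R, alpha, path) {
    out <- correlation_structure(R, sprintf(
      "%s; calibrated to median VIF %.4g via %s path (alpha=%.5f)",
      corr$provenance, target_median_vif, path, alpha))
    attr(out, "alpha") <- alpha
    attr(out, "path") <- path
    out
  }
  if (abs(v0 - target_median_vif) / target_median_vif <= rel_tol)
    return(done(R0, 0, "none"))

  if (target_median_vif < v0) {
    # de-correlation: mix towards the identity
    path_matrix <- function(a) repair_pd((1 - a) * R0 + a * diag(nrow(R0)))
    v_end <- 1
    path <- "decorrelate"
  } else {
    if (is.null(bs))
      stopf("amplification towards VIF %g requires the generating block_structure",
            target_median_vif)
    B <- repair_pd(block_pattern_matrix(bs, rep(0.995, length(bs$block_sizes))))
    path_matrix <- function(a) repair_pd((1 - a) * R0 + a * B)
    v_end <- population_median_vif(path_matrix(1))
    path <- "saturate"
    if (target_median_vif > v_end * (1 + rel_tol))
      stopf("target median VIF %g unreachable on saturation path: attainable range is [%.3g, %.3g]",
            target_median_vif, v0, v_end)
  }

  lo <- 0; hi <- 1
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    Rm <- path_matrix(mid)
    vm <- population_median_vif(Rm)
    if (abs(vm - target_median_vif) / target_median_vif <= rel_tol)
      return(done(Rm, mid, path))
    # VIF decreases with alpha on the decorrelation path, increases on saturation
    going_up <- (path == "saturate")
    if ((vm < target_median_vif) == going_up) lo <- mid else hi <- mid
  }
  stopf("VIF calibration did not converge (base %.3g, target %.3g, last %.3g)",
        v0, target_median_vif, vm)
}
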