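#' Draw from a multivariate normal with zero mean and given correlation
#'
#' @param n number of draws.
#' @param corr `correlation_structure` or correlation matrix.
#' @param seed integer seed (the global RNG state is left untouched).
#' @return n x p matrix.
#' @export
rmvn_corr <- function(n, corr, seed) {
  R <- if (inherits(corr, "correlation_structure")) corr$matrix else corr
  U <- chol(R)
  withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R))
  })
  X <- Z %*% U
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' @keywords internal
new_ground_truth <- function(intercept, coefficients, nonneg_mask) {
  stopifnot(all(is.finite(coefficients)), is.finite(intercept),
            length(nonneg_mask) == length(coefficients))
  structure(list(intercept = intercept, coefficients = coefficients,
                 nonneg_mask = nonneg_mask),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> p=%d intercept=%.3f |coef| range [%.3f, %.3f], %d non-negative-constrained\n",
              length(x$coefficients), x$intercept,
              min(abs(x$coefficients)), max(abs(x$coefficients)),
              sum(x$nonneg_mask)))
  invisible(x)
}

#' Calibrate the ground-truth intercept to a target prevalence
#'
#' Bisection on the intercept so that the Monte-Carlo mean of
#' `plogis(intercept + X theta)` over `mc_n` multivariate-normal draws equals
#' the target prevalence within 1e-3.
#'
#' @param truth a `ground_truth` model (only its coefficients are used).
#' @param corr calibrated `correlation_structure`.
#' @param target_prevalence target event probability in (0, 1).
#' @param mc_n Monte-Carlo sample size (default 200000).
#' @param seed seed for the Monte-Carlo draws.
#' @return the calibrated intercept (log-odds scalar).
#' @export
calibrate_intercept <- function(truth, corr, target_prevalence,
                                mc_n = 200000, seed = 1L) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stopf("target prevalence must lie in (0, 1)")
  eta <- drop(rmvn_corr(mc_n, corr, seed) %*% truth$coefficients)
  prev_at <- function(b0) mean(stats::plogis(b0 + eta))
  lo <- -30; hi <- 30
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    pm <- prev_at(mid)
    if (abs(pm - target_prevalence) < 1e-4) break
    if (pm < target_prevalence) lo <- mid else hi <- mid
  }
  mid
}

#' Construct a ground-truth logistic model for a setting
#'
#' Two construction modes. `"draw"`: coefficients are drawn directly —
#' organ-at-risk dose predictors from `|N(0, 0.2^2)|` (non-negative, encoding
#' the clinical prior that dose to healthy tissue does not reduce complication
#' risk) and clinical predictors from `N(0, 0.3^2)` — then rescaled by a
#' common factor so the true-model AUC on a large Monte-Carlo sample is
#' 0.75 +/- 0.01. `"ridge_distill"` additionally simulates a 10,000-record
#' seed dataset from the drawn model and adopts the coefficients of a
#' ridge-penalized logistic fit (`lambda_l2 = 1`) to that dataset, mimicking a
#' ground truth obtained by penalized regression on observed cohort data. In
#' both modes the intercept is then calibrated to the setting's target
#' prevalence with [calibrate_intercept()].
#'
#' @param corr calibrated `correlation_structure` for the setting.
#' @param setting a [setting_spec()].
#' @param mode `"ridge_distill"` (default) or `"draw"`.
#' @param seed integer seed.
#' @param target_auc target true-model AUC for the rescaling step.
#' @param mc_n Monte-Carlo size for AUC/prevalence calibration.
#' @param n_seed_data seed-dataset size for distillation.
#' @param distill_lambda ridge penalty weight used in the distillation fit.
#' @return a `ground_truth` model.
#' @export
make_ground_truth <- function(corr, setting, mode = c("ridge_distill", "draw"),
                              seed = 1L, target_auc = 0.75, mc_n = 200000,
                              n_seed_data = 10000, distill_lambda = 1.0) {
  mode <- match.arg(mode)
  p <- setting$p
  nc <- setting$block_structure$n_clinical
  nonneg <- c(rep(FALSE, nc), rep(TRUE, p - nc))
  raw <- withr::with_seed(seed, {
    b <- numeric(p)
    if (nc > 0) b[seq_len(nc)] <- stats::rnorm(nc, 0, 0.3)
    if (p > nc) b[(nc + 1):p] <- abs(stats::rnorm(p - nc, 0, 0.2))
    b
  })

  # shared Monte-Carlo draws for AUC and prevalence calibration
  mc_seed <- child_seed(seed, 1L)
  X <- rmvn_corr(mc_n, corr, mc_seed)
  eta_raw <- drop(X %*% raw)
  u <- withr::with_seed(child_seed(seed, 2L), stats::runif(mc_n))

  auc_at <- function(scale, b0) {
    pi <- stats::plogis(b0 + scale * eta_raw)
    y <- as.integer(u < pi)
    if (all(y == y[1])) return(0.5)
    auc(y, pi)
  }
  prev_at <- function(scale, b0) mean(stats::plogis(b0 + scale * eta_raw))

  b0 <- logit(setting$prevalence)
  scale <- 1
  if (max(abs(raw)) < 1e-12) {
    # degenerate all-zero model: AUC is 0.5 by construction
    scale <- 0
  } else {
    for (pass in 1:2) {
      # log-scale bisection of the common factor towards the target AUC
      lo <- -8; hi <- 8
      if (auc_at(exp(lo), b0) > target_auc || auc_at(exp(hi), b0) < target_auc)
        stopf("cannot bracket target true-model AUC %.2f", target_auc)
      for (it in seq_len(100)) {
        mid <- (lo + hi) / 2
        am <- auc_at(exp(mid), b0)
        if (abs(am - target_auc) < 0.005) break
        if (am < target_auc) lo <- mid else hi <- mid
      }
      scale <- exp(mid)
      # re-calibrate the intercept at the new scale (re-using the draws)
      blo <- -30; bhi <- 30
      for (it in seq_len(200)) {
        bmid <- (blo + bhi) / 2
        pm <- prev_at(scale, bmid)
        if (abs(pm - setting$prevalence) < 1e-4) break
        if (pm < setting$prevalence) blo <- bmid else bhi <- bmid
      }
      b0 <- bmid
    }
    if (abs(auc_at(scale, b0) - target_auc) > 0.01)
      stopf("true-model AUC calibration failed to reach %.2f +/- 0.01", target_auc)
  }
  theta <- raw * scale
  truth <- new_ground_truth(b0, theta, nonneg)

  if (mode == "ridge_distill" && scale > 0) {
    ds <- simulate_dataset(setting, truth, corr, n = n_seed_data,
                           seed = child_seed(seed, 3L))
    # predictors have unit population variance; fit on the raw scale
    fit <- fit_glm_core_r(ds$X, ds$y, lambda_l2 = distill_lambda)
    truth <- new_ground_truth(fit$intercept, fit$coefficients, nonneg)
  }

  b0_final <- calibrate_intercept(truth, corr, setting$prevalence,
                                  mc_n = mc_n, seed = child_seed(seed, 4L))
  truth$intercept <- b0_final
  truth
}

#' Monte-Carlo estimate of a ground-truth model's AUC
#'
#' @param truth `ground_truth` model.
#' @param corr `correlation_structure`.
#' @param mc_n Monte-Carlo sample size.
#' @param seed integer seed.
#' @return scalar AUC estimate.
#' @export
true_model_auc <- function(truth, corr, mc_n = 200000, seed = 1L) {
  X <- rmvn_corr(mc_n, corr, seed)
  pi <- stats::plogis(truth$intercept + drop(X %*% truth$coefficients))
  y <- withr::with_seed(child_seed(seed, 9L),
                        stats::rbinom(mc_n, 1, pi))
  auc(y, pi)
}
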