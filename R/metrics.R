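#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a randomly chosen event outranks a randomly chosen
#' non-event; ties receive half credit.
#'
#' @param y binary outcome vector.
#' @param risks predicted risks (any monotone score).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(y, risks) {
  y <- as.integer(y)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stopf("AUC requires both outcome classes")
  r <- rank(risks, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration intercept (calibration-in-the-large)
#'
#' Maximum-likelihood intercept of the logistic model
#' `y ~ a + offset(qlogis(risk))`. Zero indicates that the mean predicted
#' risk matches the observed prevalence; positive values indicate general
#' underestimation of risk.
#'
#' @param y binary outcomes.
#' @param risks predicted risks strictly in (0, 1).
#' @return scalar intercept.
#' @export
calibration_intercept <- function(y, risks) {
  lp <- logit(clip_prob(risks))
  fit <- stats::glm(y ~ 1, offset = lp, family = stats::binomial())
  if (!fit$converged) stopf("calibration intercept fit did not converge")
  unname(stats::coef(fit)[1])
}

#' Calibration slope
#'
#' Maximum-likelihood slope of the logistic recalibration model
#' `y ~ a + b * qlogis(risk)`. One is ideal; below one indicates too extreme
#' predictions.
#'
#' @inheritParams calibration_intercept
#' @return scalar slope.
#' @export
calibration_slope <- function(y, risks) {
  lp <- logit(clip_prob(risks))
  if (stats::sd(lp) < 1e-12) stopf("constant linear predictor: slope undefined")
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  if (!fit$converged) stopf("calibration slope fit did not converge")
  unname(stats::coef(fit)[2])
}

#' Nagelkerke R-squared
#'
#' Cox-Snell `R^2 = 1 - exp((2/n)(LL0 - LL1))` rescaled by its maximum
#' `1 - exp((2/n) LL0)`, where `LL0` is the intercept-only log-likelihood and
#' `LL1` the log-likelihood of the supplied risks.
#'
#' @inheritParams calibration_intercept
#' @return scalar `<= 1`.
#' @export
nagelkerke_r2 <- function(y, risks) {
  y <- as.integer(y)
  n <- length(y)
  if (length(unique(y)) < 2) stopf("Nagelkerke R2 requires both classes")
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  pi <- clip_prob(risks)
  ll1 <- sum(y * log(pi) + (1 - y) * log(1 - pi))
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2_cs / (1 - exp((2 / n) * ll0))
}

#' Coefficient estimation error
#'
#' Mean absolute and mean squared error between estimated and true
#' coefficients, intercept excluded. Both vectors must be on the standardized
#' predictor scale.
#'
#' @param est a `fitted_clm` or plain coefficient vector.
#' @param truth a `ground_truth` model or plain coefficient vector.
#' @return list with `mae` and `mse`.
#' @export
coefficient_error <- function(est, truth) {
  b <- if (inherits(est, "fitted_clm")) est$coefficients else est
  t <- if (inherits(truth, "ground_truth")) truth$coefficients else truth
  if (length(b) != length(t)) stopf("coefficient vectors differ in length")
  d <- b - t
  list(mae = mean(abs(d)), mse = mean(d^2))
}

#' Thresholded coefficient sign
#'
#' `-1` iff `x < -0.01`, `+1` iff `x > 0.01`, `0` otherwise (strict
#' inequalities); coefficients of magnitude at most 0.01 count as excluded
#' from the model.
#'
#' @param x numeric vector.
#' @return integer vector over `{-1, 0, 1}`.
#' @export
sgn <- function(x) {
  stopifnot(all(is.finite(x)))
  ifelse(x > 0.01, 1L, ifelse(x < -0.01, -1L, 0L))
}

#' Jaccard index of coefficient signs between two model fits
#'
#' Each coefficient vector is reduced to the set of (index, sign) pairs with
#' nonzero thresholded sign (zero = excluded predictor). The index is the
#' intersection size over the union size; an index carrying opposite signs in
#' the two fits contributes two union elements and none to the intersection.
#' Two all-excluded models agree perfectly (index 1).
#'
#' @param theta_i,theta_j equal-length coefficient vectors.
#' @param count_zero_agreement if TRUE, zero signs are treated as a third
#'   element class (so shared exclusions count as agreement) — a sensitivity
#'   variant of the default set semantics.
#' @return scalar in `[0, 1]`.
#' @export
jaccard_sign_index <- function(theta_i, theta_j,
                               count_zero_agreement = FALSE) {
  if (length(theta_i) != length(theta_j))
    stopf("coefficient vectors differ in length")
  si <- sgn(theta_i); sj <- sgn(theta_j)
  if (count_zero_agreement) {
    inter <- sum(si == sj)
    uni <- length(si) + sum(si != sj)
  } else {
    inter <- sum(si == sj & si != 0L)
    uni <- sum(si != 0L) + sum(sj != 0L) - inter
  }
  if (uni == 0) return(1)
  inter / uni
}

#' Mean Jaccard index of coefficient signs (MJICS)
#'
#' Predictor-selection stability over repeated model fits: the mean of
#' [jaccard_sign_index()] over all unordered pairs of repetitions.
#'
#' @param coefficient_vectors list (or matrix with one row per repetition) of
#'   length-p coefficient vectors.
#' @param count_zero_agreement passed to [jaccard_sign_index()].
#' @return scalar in `[0, 1]`.
#' @export
mjics <- function(coefficient_vectors, count_zero_agreement = FALSE) {
  if (is.matrix(coefficient_vectors))
    coefficient_vectors <- asplit(coefficient_vectors, 1)
  m <- length(coefficient_vectors)
  if (m < 2) stopf("MJICS requires at least two repetitions")
  tot <- 0; k <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    tot <- tot + jaccard_sign_index(coefficient_vectors[[i]],
                                    coefficient_vectors[[j]],
                                    count_zero_agreement)
    k <- k + 1
  }
  tot / k
}

#' Lowess-smoothed calibration curve
#'
#' Locally weighted scatterplot smoothing of the observed outcome against the
#' predicted risk, evaluated on a grid of risk values. For a perfectly
#' calibrated model at large n the curve tracks the diagonal.
#'
#' @param y binary outcomes (n >= 20).
#' @param risks predicted risks in (0, 1); must not be constant.
#' @param bandwidth lowess smoother span (default 2/3).
#' @param grid_size number of grid points.
#' @return data.frame with columns `risk` and `observed`.
#' @export
calibration_curve <- function(y, risks, bandwidth = 2/3, grid_size = 50) {
  if (length(y) < 20) stopf("calibration curve requires n >= 20")
  if (stats::sd(risks) < 1e-12)
    stopf("constant predicted risk: calibration grid degenerate")
  # iter = 0: the robustness reweighting misbehaves on binary outcomes
  sm <- stats::lowess(risks, y, f = bandwidth, iter = 0)
  grid <- seq(min(risks), max(risks), length.out = grid_size)
  obs <- stats::approx(sm$x, sm$y, xout = grid, rule = 2, ties = mean)$y
  data.frame(risk = grid, observed = pmin(pmax(obs, 0), 1))
}

#' All validation metrics of one fitted model
#'
#' @param model a `fitted_clm`.
#' @param val_data standardized validation [sim_dataset()] (on the model's
#'   scale).
#' @param truth optional `ground_truth` for coefficient error.
#' @return named list: `auc`, `cal_intercept`, `cal_slope`, `r2_nagelkerke`,
#'   and (if truth given) `mae`, `mse`.
#' @export
metric_set <- function(model, val_data, truth = NULL) {
  risks <- predict_risk(model, val_data$X)
  out <- list(auc = auc(val_data$y, risks),
              cal_intercept = calibration_intercept(val_data$y, risks),
              cal_slope = calibration_slope(val_data$y, risks),
              r2_nagelkerke = nagelkerke_r2(val_data$y, risks))
  if (!is.null(truth)) {
    ce <- coefficient_error(model, truth)
    out$mae <- ce$mae
    out$mse <- ce$mse
  }
  out
}
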