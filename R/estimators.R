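METHOD_LABELS <- c("LR", "Lasso", "Ridge", "ElasticNet", "Dropout",
                   "PCLR", "LAELR", "LR_NN")

#' Construct a hyperparameter set
#'
#' Only the fields relevant to a method should be set: `lambda_l1`
#' (Lasso/ElasticNet), `lambda_l2` (Ridge/ElasticNet), `delta` (Dropout,
#' in `[0, 1)`), `d_pca` (PCLR), `d_lae` and `lambda_lae` (LAELR).
#'
#' @param lambda_l1,lambda_l2,lambda_lae non-negative penalty weights.
#' @param delta dropout ratio in `[0, 1)`.
#' @param d_pca,d_lae component counts in `1..p`.
#' @return an object of class `hyperparameters`.
#' @export
hyperparameters <- function(lambda_l1 = NULL, lambda_l2 = NULL, delta = NULL,
                            d_pca = NULL, d_lae = NULL, lambda_lae = NULL) {
  hp <- list(lambda_l1 = lambda_l1, lambda_l2 = lambda_l2, delta = delta,
             d_pca = d_pca, d_lae = d_lae, lambda_lae = lambda_lae)
  hp <- hp[!vapply(hp, is.null, TRUE)]
  for (nm in c("lambda_l1", "lambda_l2", "lambda_lae"))
    if (!is.null(hp[[nm]]) && hp[[nm]] < 0) stopf("%s must be >= 0", nm)
  if (!is.null(hp$delta) && (hp$delta < 0 || hp$delta >= 1))
    stopf("delta must lie in [0, 1)")
  structure(hp, class = "hyperparameters")
}

#' Standardize a dataset
#'
#' Centers and scales every predictor column to zero mean and unit variance on
#' the training data, returning the standardized dataset and a transform that
#' must be applied unchanged to any validation data.
#'
#' @param train a [sim_dataset()].
#' @return list with `data` (standardized [sim_dataset()]) and `transform`
#'   (list of `means`, `sds`).
#' @export
standardize <- function(train) {
  stopifnot(inherits(train, "sim_dataset"))
  means <- colMeans(train$X)
  sds <- apply(train$X, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s",
          paste(colnames(train$X)[sds == 0], collapse = ", "))
  Xs <- sweep(sweep(train$X, 2, means, "-"), 2, sds, "/")
  list(data = sim_dataset(Xs, train$y, means = means, sds = sds,
                          is_standardized = TRUE),
       transform = list(means = means, sds = sds))
}

#' Apply a standardization transform
#'
#' @param transform transform from [standardize()].
#' @param data a [sim_dataset()] or plain matrix on the original scale.
#' @return object of the same type on the standardized scale.
#' @export
apply_standardization <- function(transform, data) {
  f <- function(X) sweep(sweep(X, 2, transform$means, "-"), 2,
                         transform$sds, "/")
  if (inherits(data, "sim_dataset"))
    sim_dataset(f(data$X), data$y, means = transform$means,
                sds = transform$sds, is_standardized = TRUE)
  else f(as.matrix(data))
}

#' Mean negative log-likelihood of a logistic model
#'
#' Mean over records of `-(y log pi + (1-y) log(1-pi))` with
#' `pi = plogis(intercept + X coefficients)`, numerically clipped at
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param intercept scalar.
#' @param coefficients length-p vector.
#' @param X n x p matrix.
#' @param y binary outcome vector.
#' @return non-negative scalar.
#' @export
negative_log_likelihood <- function(intercept, coefficients, X, y) {
  pi <- clip_prob(stats::plogis(intercept + drop(as.matrix(X) %*% coefficients)))
  -mean(y * log(pi) + (1 - y) * log(1 - pi))
}

#' @keywords internal
new_fitted_model <- function(method, intercept, coefficients, hp, converged,
                             n_iterations, extra = list()) {
  if (!all(is.finite(coefficients)) || !is.finite(intercept))
    stopf("non-finite parameters in fitted %s model", method)
  structure(c(list(method = method, intercept = intercept,
                   coefficients = coefficients, hyperparameters = hp,
                   converged = converged, n_iterations = n_iterations),
              extra),
            class = "fitted_clm")
}

#' @export
print.fitted_clm <- function(x, ...) {
  hp <- unlist(x$hyperparameters)
  cat(sprintf("<fitted_clm %s> p=%d intercept=%.3f%s%s\n", x$method,
              length(x$coefficients), x$intercept,
              if (length(hp)) paste0(" [", paste(names(hp), signif(hp, 3),
                                                 sep = "=", collapse = ", "),
                                     "]") else "",
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @keywords internal
check_standardized <- function(data) {
  if (!inherits(data, "sim_dataset")) stopf("data must be a sim_dataset")
  if (!isTRUE(data$is_standardized))
    stopf("estimators require standardized data: call standardize() first")
}

# thin wrapper over the C++ core operating on a plain matrix (used both by
# fit() and by ground-truth distillation, where data are already on the
# population scale)
#' @keywords internal
fit_glm_core_r <- function(X, y, lambda_l1 = 0, lambda_l2 = 0, delta = 0,
                           nonneg_mask = NULL, seed = 1L, max_iter = 10000L,
                           tol = 1e-8, patience = 10L, trace = FALSE) {
  nonneg_idx0 <- if (is.null(nonneg_mask)) integer(0) else
    which(as.logical(nonneg_mask)) - 1L
  if (delta > 0) max_iter <- min(max_iter, 4000L)
  res <- cpp_fit_glm(as.matrix(X), as.numeric(y), lambda_l1, lambda_l2,
                     delta, as.integer(nonneg_idx0), as.integer(seed),
                     as.integer(max_iter), tol, as.integer(patience), trace)
  res$coefficients <- drop(res$coefficients)
  names(res$coefficients) <- colnames(X)
  res
}

#' Fit one of the compared logistic prediction methods
#'
#' All methods minimize a per-record objective `mean NLL + penalty / n` with
#' the shared first-order core and report intercept plus coefficients on the
#' standardized original-predictor scale:
#' \describe{
#'   \item{LR}{plain maximum likelihood.}
#'   \item{Lasso}{`lambda_l1 * sum |beta|` handled by a proximal
#'     soft-threshold (exact zeros attainable).}
#'   \item{Ridge}{`lambda_l2 * sum beta^2`.}
#'   \item{ElasticNet}{both penalties.}
#'   \item{Dropout}{at each iteration every predictor is zeroed independently
#'     with probability `delta` and retained columns are rescaled by
#'     `1/(1-delta)` (inverted dropout); the final weights are used as-is at
#'     prediction time.}
#'   \item{LR_NN}{maximum likelihood with the coefficients flagged by
#'     `nonneg_mask` projected onto `[0, Inf)` after every step (hard
#'     non-negativity via gradient projection).}
#' }
#' The intercept is never penalized, dropped, or constrained. PCLR and LAELR
#' have dedicated entry points ([fit_pclr()], [fit_laelr()]) but are also
#' dispatched from here.
#'
#' @param method one of `"LR"`, `"Lasso"`, `"Ridge"`, `"ElasticNet"`,
#'   `"Dropout"`, `"PCLR"`, `"LAELR"`, `"LR_NN"`.
#' @param data a standardized [sim_dataset()].
#' @param hp a [hyperparameters()] object with the fields the method needs.
#' @param seed seed for the stochastic methods (Dropout masking, LAELR
#'   initialization); ignored by deterministic methods.
#' @param nonneg_mask logical length-p vector for LR_NN (typically the
#'   generator's dose-predictor mask).
#' @param trace if TRUE the per-iteration objective is attached as attribute
#'   `objective_trace`.
#' @return a `fitted_clm` model.
#' @export
fit <- function(method, data, hp = hyperparameters(), seed = 1L,
                nonneg_mask = NULL, trace = FALSE) {
  method <- match.arg(method, METHOD_LABELS)
  check_standardized(data)
  if (method == "PCLR") return(fit_pclr(data, hp, trace = trace))
  if (method == "LAELR") return(fit_laelr(data, hp, seed = seed, trace = trace))

  l1 <- hp$lambda_l1 %||% 0
  l2 <- hp$lambda_l2 %||% 0
  delta <- hp$delta %||% 0
  mask <- NULL
  if (method == "LR") { l1 <- 0; l2 <- 0; delta <- 0 }
  if (method == "Lasso" && is.null(hp$lambda_l1))
    stopf("Lasso requires lambda_l1")
  if (method == "Ridge" && is.null(hp$lambda_l2))
    stopf("Ridge requires lambda_l2")
  if (method == "ElasticNet" && (is.null(hp$lambda_l1) || is.null(hp$lambda_l2)))
    stopf("ElasticNet requires lambda_l1 and lambda_l2")
  if (method == "Dropout" && is.null(hp$delta))
    stopf("Dropout requires delta")
  if (method == "Lasso") { l2 <- 0; delta <- 0 }
  if (method == "Ridge") { l1 <- 0; delta <- 0 }
  if (method == "ElasticNet") delta <- 0
  if (method == "Dropout") { l1 <- 0; l2 <- 0 }
  if (method == "LR_NN") {
    l1 <- 0; l2 <- 0; delta <- 0
    if (is.null(nonneg_mask))
      stopf("LR_NN requires a nonneg_mask identifying the constrained predictors")
    mask <- nonneg_mask
  }

  res <- fit_glm_core_r(data$X, data$y, lambda_l1 = l1, lambda_l2 = l2,
                        delta = delta, nonneg_mask = mask, seed = seed,
                        trace = trace)
  if (!res$converged)
    warnf("%s fit did not converge within %d iterations", method,
          res$n_iterations)
  m <- new_fitted_model(method, res$intercept, res$coefficients, hp,
                        res$converged, res$n_iterations,
                        extra = list(nonneg_mask = mask))
  if (trace) attr(m, "objective_trace") <- res$objective_trace
  m
}

#' Principal component logistic regression
#'
#' Computes the leading `d_pca` principal-component loadings of the
#' standardized training predictors (eigenvectors of the sample correlation
#' matrix in descending eigenvalue order, each loading's largest-magnitude
#' entry made positive), fits an unpenalized logistic regression of the
#' outcome on the component scores, and back-projects to an equivalent
#' logistic model on the original predictors: `coefficients = V gamma`, with
#' the intercept unchanged (the score columns are zero-mean).
#'
#' @param data standardized [sim_dataset()].
#' @param hp [hyperparameters()] with `d_pca`.
#' @param trace attach the stage-2 objective trace.
#' @return a `fitted_clm` with extra fields `loadings` and `gamma`.
#' @export
fit_pclr <- function(data, hp, trace = FALSE) {
  check_standardized(data)
  d <- hp$d_pca
  if (is.null(d)) stopf("PCLR requires d_pca")
  p <- ncol(data$X)
  e <- eigen(stats::cor(data$X), symmetric = TRUE)
  rank <- sum(e$values > 1e-10)
  if (d < 1 || d > rank)
    stopf("d_pca must lie in 1..rank (rank %d, got %d)", rank, d)
  V <- e$vectors[, seq_len(d), drop = FALSE]
  # fix component signs: largest-magnitude entry of each loading positive
  for (j in seq_len(d)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  S <- data$X %*% V
  res <- fit_glm_core_r(S, data$y, trace = trace)
  beta <- drop(V %*% res$coefficients)
  names(beta) <- colnames(data$X)
  m <- new_fitted_model("PCLR", res$intercept, beta, hp, res$converged,
                        res$n_iterations,
                        extra = list(loadings = V, gamma = res$coefficients))
  if (trace) attr(m, "objective_trace") <- res$objective_trace
  m
}

#' Linear autoencoder logistic regression
#'
#' Jointly minimizes the outcome negative log-likelihood of a logistic model
#' on `d_lae` linear components and the mean squared reconstruction error of
#' the predictors from those components,
#' `NLL(y, plogis(b + (X W_enc) w)) + lambda_lae * mean((X - (X W_enc) W_dec)^2)`,
#' with the decoder tied to the encoder transpose (`W_dec = t(W_enc)`) and
#' seeded random-normal initialization (scale 0.1). Tying removes the
#' re-parametrization freedom an untied pair has on perfectly collinear
#' predictors, so the back-projected coefficients `W_enc w` are well defined.
#'
#' @param data standardized [sim_dataset()].
#' @param hp [hyperparameters()] with `d_lae` and `lambda_lae`.
#' @param seed seed for the initialization.
#' @param trace attach the objective trace.
#' @return a `fitted_clm` with extra fields `W_enc`, `W_dec`, `w`.
#' @export
fit_laelr <- function(data, hp, seed = 1L, trace = FALSE) {
  check_standardized(data)
  d <- hp$d_lae
  lam <- hp$lambda_lae
  if (is.null(d) || is.null(lam)) stopf("LAELR requires d_lae and lambda_lae")
  p <- ncol(data$X)
  if (d < 1 || d > p) stopf("d_lae must lie in 1..p")
  res <- cpp_fit_laelr(data$X, as.numeric(data$y), as.integer(d), lam,
                       as.integer(seed), 0.1, 10000L, 1e-8, 10L, trace)
  if (!res$converged)
    warnf("LAELR fit did not converge within %d iterations", res$n_iterations)
  beta <- drop(res$W_enc %*% res$w)
  names(beta) <- colnames(data$X)
  m <- new_fitted_model("LAELR", res$intercept, beta, hp, res$converged,
                        res$n_iterations,
                        extra = list(W_enc = res$W_enc, W_dec = res$W_dec,
                                     w = drop(res$w)))
  if (trace) attr(m, "objective_trace") <- res$objective_trace
  m
}

#' Predicted risks of a fitted model
#'
#' @param model a `fitted_clm`.
#' @param X matrix on the model's standardized predictor scale.
#' @return vector of probabilities strictly inside (0, 1).
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "fitted_clm"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients))
    stopf("X has %d columns but the model has %d coefficients", ncol(X),
          length(model$coefficients))
  clip_prob(stats::plogis(model$intercept + drop(X %*% model$coefficients)))
}

#' Export a fitted model (with its standardization) as JSON
#'
#' @param model a `fitted_clm`.
#' @param transform standardization transform from [standardize()].
#' @param path output path; if NULL the JSON string is returned.
#' @return the path (or JSON string), invisibly.
#' @export
model_to_json <- function(model, transform = NULL, path = NULL) {
  stopifnot(inherits(model, "fitted_clm"))
  obj <- list(method = model$method,
              hyperparameters = unclass(model$hyperparameters),
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              standardization = transform)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(js))
  writeLines(js, path)
  invisible(path)
}

#' Import a fitted model from JSON
#'
#' @param path path to a file written by [model_to_json()].
#' @return list with `model` (a `fitted_clm`) and `transform`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  hp <- do.call(hyperparameters, as.list(obj$hyperparameters))
  model <- new_fitted_model(obj$method, obj$intercept,
                            unlist(obj$coefficients), hp, TRUE, 0L)
  list(model = model, transform = obj$standardization)
}

#' Express a fitted model on the raw predictor scale
#'
#' Converts standardized-scale coefficients back to the raw scale
#' (`beta / sd`, intercept adjusted by `-sum(beta * mean / sd)`).
#'
#' @param model a `fitted_clm` fitted on standardized data.
#' @param transform the standardization transform used.
#' @return list with `intercept` and `coefficients` on the raw scale.
#' @export
raw_scale_coefficients <- function(model, transform) {
  b <- model$coefficients / transform$sds
  list(intercept = model$intercept - sum(b * transform$means),
       coefficients = b)
}
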