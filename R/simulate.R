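#' Construct a dataset object
#'
#' @param X n x p numeric predictor matrix.
#' @param y length-n binary (0/1) outcome vector.
#' @param means,sds standardization parameters (NULL until standardized).
#' @param is_standardized logical flag.
#' @return object of class `sim_dataset`.
#' @export
sim_dataset <- function(X, y, means = NULL, sds = NULL,
                        is_standardized = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X and y sizes differ")
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  if (!is.null(sds) && any(sds <= 0)) stopf("sds must be strictly positive")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = as.integer(y), means = means, sds = sds,
                 is_standardized = is_standardized),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> n=%d p=%d events=%d (%.1f%%)%s\n",
              nrow(x$X), ncol(x$X), sum(x$y), 100 * mean(x$y),
              if (x$is_standardized) " [standardized]" else ""))
  invisible(x)
}

#' Simulate a development or validation dataset
#'
#' Draws `X ~ MVN(0, corr)` and `y_i ~ Bernoulli(plogis(b0 + x_i theta))`.
#' Returns unstandardized data; standardization is a modelling step performed
#' on the development sample only (see [standardize()]).
#'
#' @param setting a [setting_spec()] (used for the predictor count).
#' @param truth `ground_truth` model.
#' @param corr calibrated `correlation_structure`.
#' @param n sample size.
#' @param seed integer seed; the same seed reproduces the dataset bitwise.
#' @return a [sim_dataset()].
#' @export
simulate_dataset <- function(setting, truth, corr, n, seed) {
  if (n < 1) stopf("n must be >= 1")
  X <- rmvn_corr(n, corr, seed)
  pi <- stats::plogis(truth$intercept + drop(X %*% truth$coefficients))
  y <- withr::with_seed(child_seed(seed, 7L), stats::rbinom(n, 1, pi))
  sim_dataset(X, y)
}

#' Events per variable
#'
#' Number of outcome events divided by the number of candidate predictors.
#'
#' @param data a [sim_dataset()].
#' @return non-negative scalar.
#' @export
epv <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  sum(data$y) / ncol(data$X)
}

#' Write a dataset as CSV
#'
#' Header row `x1,...,xp,y`; one record per row.
#'
#' @param data a [sim_dataset()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "sim_dataset"))
  df <- as.data.frame(data$X)
  df$y <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects numeric predictor columns plus a binary outcome column.
#'
#' @param path CSV path.
#' @param outcome outcome column name (default `"y"`).
#' @return a [sim_dataset()].
#' @export
read_dataset_csv <- function(path, outcome = "y") {
  df <- utils::read.csv(path)
  if (!outcome %in% names(df)) stopf("outcome column '%s' not found", outcome)
  y <- df[[outcome]]
  if (anyNA(df)) stopf("missing values found: impute before analysis (handling of missing data is out of scope)")
  if (!all(y %in% c(0, 1))) stopf("outcome column '%s' is not binary 0/1", outcome)
  X <- as.matrix(df[setdiff(names(df), outcome)])
  if (!is.numeric(X)) stopf("non-numeric predictor columns present")
  sim_dataset(X, y)
}
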