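#' Repeated cross-validation analysis of a user-supplied dataset
#'
#' For observed cohort data (no ground truth), each measure is estimated by
#' repeated stratified 5-fold cross-validation: in every repeat, a fresh
#' stratified fold split is drawn; each fold's training part (4/5 of the
#' records) is used for tuning and fitting, and the held-out fifth for
#' evaluation. Coefficient MAE is omitted (no true coefficients); MJICS is
#' computed across all fold models of a method.
#'
#' @param path CSV path: numeric predictor columns plus a binary outcome
#'   column, no missing values.
#' @param outcome outcome column name.
#' @param config a [study_config()]; `n_rep` is the number of repeated fold
#'   splits, `methods`, `budget` and `master_seed` are used as in the
#'   simulation study.
#' @param k number of folds (default 5).
#' @param nonneg_mask optional logical mask of non-negativity-constrained
#'   predictors for LR_NN (default: none).
#' @return a `study_results` list (setting label `"real_data"`).
#' @export
run_real_data_mode <- function(path, outcome = "y", config, k = 5,
                               nonneg_mask = NULL) {
  data <- read_dataset_csv(path, outcome = outcome)
  p <- ncol(data$X)
  if (is.null(nonneg_mask)) nonneg_mask <- rep(FALSE, p)
  rows <- list(); hp_rows <- list()
  coefs <- lapply(config$methods, function(m) list())
  names(coefs) <- config$methods

  for (r in seq_len(config$n_rep)) {
    seed_r <- child_seed(config$master_seed, 77L, r)
    fold <- stratified_folds(data$y, k, child_seed(seed_r, 1L))
    for (f in seq_len(k)) {
      tr_idx <- which(fold != f); te_idx <- which(fold == f)
      tr <- sim_dataset(data$X[tr_idx, , drop = FALSE], data$y[tr_idx])
      te_y <- data$y[te_idx]
      st <- standardize(tr)
      for (mi in seq_along(config$methods)) {
        m <- config$methods[mi]
        tu <- tune(m, tr, budget = config$budget,
                   seed = child_seed(seed_r, 2L, f, mi),
                   optimizer = config$tuning_optimizer,
                   nonneg_mask = nonneg_mask)
        model <- suppressWarnings(
          fit(m, st$data, tu$best, seed = child_seed(seed_r, 3L, f, mi),
              nonneg_mask = nonneg_mask))
        Xte <- apply_standardization(st$transform,
                                     data$X[te_idx, , drop = FALSE])
        risks <- predict_risk(model, Xte)
        vals <- c(auc = safe_metric(auc(te_y, risks)),
                  cal_intercept = safe_metric(calibration_intercept(te_y, risks)),
                  cal_slope = safe_metric(calibration_slope(te_y, risks)),
                  r2_nagelkerke = safe_metric(nagelkerke_r2(te_y, risks)))
        rows[[length(rows) + 1]] <- data.frame(
          setting = "real_data", method = m,
          repetition = (r - 1L) * k + f,
          metric = names(vals), value = unname(vals))
        coefs[[m]][[length(coefs[[m]]) + 1]] <- model$coefficients
        hp <- unlist(tu$best)
        if (length(hp))
          hp_rows[[length(hp_rows) + 1]] <- data.frame(
            setting = "real_data", method = m, repetition = (r - 1L) * k + f,
            hyperparameter = names(hp), value = unname(hp))
      }
    }
  }
  for (m in config$methods) {
    rows[[length(rows) + 1]] <- data.frame(
      setting = "real_data", method = m, repetition = NA_integer_,
      metric = "mjics", value = mjics(coefs[[m]]))
  }
  structure(list(results = do.call(rbind, rows),
                 hyperparameters = do.call(rbind, hp_rows),
                 coefficients = coefs),
            class = "study_results")
}
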