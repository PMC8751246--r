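#' Configuration of a simulation study
#'
#' @param settings list of [setting_spec()] (default: the shipped catalogue).
#' @param methods method labels to compare (default: all eight).
#' @param n_rep number of repetitions per setting (>= 2; default 100).
#' @param n_val validation sample size override (NULL keeps each setting's).
#' @param budget tuning budget per repetition and method (default 30).
#' @param master_seed master seed; all child streams derive from it.
#' @param ci_level confidence level for the percentile intervals.
#' @param gt_mode ground-truth construction mode (see [make_ground_truth()]).
#' @param tuning_optimizer `"bo"` or `"random"` (see [tune()]).
#' @param verbose log per-repetition timing messages.
#' @return a `study_config` list.
#' @export
study_config <- function(settings = default_settings(),
                         methods = METHOD_LABELS, n_rep = 100,
                         n_val = NULL, budget = 30, master_seed = 1L,
                         ci_level = 0.95, gt_mode = "ridge_distill",
                         tuning_optimizer = "bo", verbose = FALSE) {
  if (n_rep < 2) stopf("n_rep must be >= 2 (MJICS needs pairs)")
  bad <- setdiff(methods, METHOD_LABELS)
  if (length(bad)) stopf("unknown method(s): %s", paste(bad, collapse = ", "))
  if (inherits(settings, "setting_spec")) settings <- list(settings)
  structure(list(settings = settings, methods = methods,
                 n_rep = as.integer(n_rep), n_val = n_val,
                 budget = as.integer(budget),
                 master_seed = as.integer(master_seed),
                 ci_level = ci_level, gt_mode = gt_mode,
                 tuning_optimizer = tuning_optimizer, verbose = verbose),
            class = "study_config")
}

#' @keywords internal
safe_metric <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

#' Run all repetitions of one setting
#'
#' For each repetition: derive child seeds, simulate development and
#' validation data from the same calibrated distributions, tune each method on
#' the development data only, refit on the full development data, and evaluate
#' on the validation data. After all repetitions, MJICS is computed per method
#' from the repetition coefficient vectors. A failed repetition is re-drawn
#' with a fresh child seed (at most 3 retries) before a hard error.
#'
#' @param setting a [setting_spec()].
#' @param config a [study_config()].
#' @param artifacts optional precomputed [build_setting_artifacts()] output.
#' @param setting_index index used for child-seed derivation.
#' @return a `study_results` list with elements `results` (long-format
#'   data.frame: setting, method, repetition, metric, value),
#'   `hyperparameters` (one row per setting, method, repetition) and
#'   `coefficients` (list of per-method coefficient matrices).
#' @export
run_setting <- function(setting, config, artifacts = NULL,
                        setting_index = 1L) {
  stopifnot(inherits(setting, "setting_spec"), inherits(config, "study_config"))
  if (is.null(artifacts))
    artifacts <- build_setting_artifacts(setting, gt_mode = config$gt_mode)
  corr <- artifacts$corr; truth <- artifacts$truth
  n_val <- config$n_val %||% setting$n_val
  nonneg <- truth$nonneg_mask

  rows <- list(); hp_rows <- list()
  coefs <- lapply(config$methods, function(m)
    matrix(NA_real_, config$n_rep, setting$p))
  names(coefs) <- config$methods

  for (r in seq_len(config$n_rep)) {
    t0 <- proc.time()[3]
    for (attempt in 0:3) {
      if (attempt == 3) stopf("repetition %d of setting %s failed 3 times",
                              r, setting$name)
      seed_r <- child_seed(config$master_seed, setting_index, r,
                           1000L * attempt)
      ok <- tryCatch({
        dev <- simulate_dataset(setting, truth, corr, setting$n_dev,
                                seed = child_seed(seed_r, 1L))
        val <- simulate_dataset(setting, truth, corr, n_val,
                                seed = child_seed(seed_r, 2L))
        st <- standardize(dev)
        val_s <- apply_standardization(st$transform, val)
        for (mi in seq_along(config$methods)) {
          m <- config$methods[mi]
          tr <- tune(m, dev, budget = config$budget,
                     seed = child_seed(seed_r, 3L, mi),
                     optimizer = config$tuning_optimizer,
                     nonneg_mask = nonneg)
          model <- suppressWarnings(
            fit(m, st$data, tr$best, seed = child_seed(seed_r, 4L, mi),
                nonneg_mask = nonneg))
          risks <- predict_risk(model, val_s$X)
          vals <- c(auc = safe_metric(auc(val$y, risks)),
                    cal_intercept = safe_metric(calibration_intercept(val$y, risks)),
                    cal_slope = safe_metric(calibration_slope(val$y, risks)),
                    r2_nagelkerke = safe_metric(nagelkerke_r2(val$y, risks)))
          ce <- coefficient_error(model, truth)
          vals <- c(vals, mae = ce$mae, mse = ce$mse)
          rows[[length(rows) + 1]] <- data.frame(
            setting = setting$name, method = m, repetition = r,
            metric = names(vals), value = unname(unlist(vals)))
          coefs[[m]][r, ] <- model$coefficients
          hp <- unlist(tr$best)
          if (length(hp))
            hp_rows[[length(hp_rows) + 1]] <- data.frame(
              setting = setting$name, method = m, repetition = r,
              hyperparameter = names(hp), value = unname(hp))
        }
        TRUE
      }, error = function(e) {
        message(sprintf("setting %s rep %d attempt %d failed: %s",
                        setting$name, r, attempt + 1, conditionMessage(e)))
        FALSE
      })
      if (ok) break
    }
    if (config$verbose)
      message(sprintf("[%s] rep %d/%d done in %.1fs", setting$name, r,
                      config$n_rep, proc.time()[3] - t0))
  }

  for (m in config$methods) {
    rows[[length(rows) + 1]] <- data.frame(
      setting = setting$name, method = m, repetition = NA_integer_,
      metric = "mjics", value = mjics(coefs[[m]]))
  }
  structure(list(results = do.call(rbind, rows),
                 hyperparameters = do.call(rbind, hp_rows),
                 coefficients = coefs,
                 artifacts = artifacts),
            class = "study_results")
}

#' Run the full simulation study
#'
#' Executes [run_setting()] for every setting in the configuration and binds
#' the results. Fully reproducible under a fixed `master_seed`.
#'
#' @param config a [study_config()].
#' @return a `study_results` list; `coefficients` and `artifacts` become
#'   per-setting named lists.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  per <- lapply(seq_along(config$settings), function(i) {
    s <- config$settings[[i]]
    if (config$verbose) message(sprintf("=== setting %s ===", s$name))
    run_setting(s, config, setting_index = i)
  })
  names(per) <- vapply(config$settings, `[[`, "", "name")
  structure(list(results = do.call(rbind, lapply(per, `[[`, "results")),
                 hyperparameters = do.call(rbind,
                                           lapply(per, `[[`, "hyperparameters")),
                 coefficients = lapply(per, `[[`, "coefficients"),
                 artifacts = lapply(per, `[[`, "artifacts")),
            class = "study_results")
}

#' Summarize study results with percentile confidence intervals
#'
#' Per (setting, method, metric): the mean over repetitions and a simple
#' percentile interval (2.5/97.5 quantiles for `ci_level = 0.95`).
#'
#' @param results a `study_results` or its long-format `results` data.frame.
#' @param ci_level confidence level.
#' @return data.frame with columns setting, method, metric, mean, lower,
#'   upper, n.
#' @export
summarize_results <- function(results, ci_level = 0.95) {
  df <- if (inherits(results, "study_results")) results$results else results
  if (!nrow(df)) stopf("empty results")
  a <- (1 - ci_level) / 2
  keys <- unique(df[c("setting", "method", "metric")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    v <- df$value[df$setting == keys$setting[i] &
                  df$method == keys$method[i] &
                  df$metric == keys$metric[i]]
    v <- v[is.finite(v)]
    data.frame(keys[i, ], mean = mean(v),
               lower = unname(stats::quantile(v, a)),
               upper = unname(stats::quantile(v, 1 - a)),
               n = length(v))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write study results as long-format CSV
#'
#' @param results a `study_results`.
#' @param path output path for the metric rows.
#' @param hp_path optional output path for the hyperparameter rows.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path, hp_path = NULL) {
  stopifnot(inherits(results, "study_results"))
  utils::write.csv(results$results, path, row.names = FALSE)
  if (!is.null(hp_path))
    utils::write.csv(results$hyperparameters, hp_path, row.names = FALSE)
  invisible(path)
}
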