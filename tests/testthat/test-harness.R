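test_that("run_setting fulfils the row-counting contract", {
  s <- tiny_setting()
  art <- build_setting_artifacts(s, gt_mode = "draw")
  cfg <- study_config(settings = list(s), methods = "LR", n_rep = 2,
                      n_val = 300, master_seed = 5)
  res <- run_setting(s, cfg, artifacts = art)
  df <- res$results
  for (m in c("auc", "cal_intercept", "cal_slope", "r2_nagelkerke", "mae",
              "mse"))
    expect_identical(sum(df$metric == m), 2L, label = m)
  expect_identical(sum(df$metric == "mjics"), 1L)
  expect_true(all(is.na(df$repetition[df$metric == "mjics"])))
})

test_that("the study is deterministic and blind to the validation stream", {
  s <- tiny_setting()
  art <- build_setting_artifacts(s, gt_mode = "draw")
  cfg <- study_config(settings = list(s), methods = c("LR", "Ridge"),
                      n_rep = 2, n_val = 300, budget = 5, master_seed = 42)
  r1 <- run_setting(s, cfg, artifacts = art)
  r2 <- run_setting(s, cfg, artifacts = art)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$coefficients, r2$coefficients)

  # changing only the validation size leaves every fitted model untouched:
  # tuning and fitting see development data only
  cfg2 <- study_config(settings = list(s), methods = c("LR", "Ridge"),
                       n_rep = 2, n_val = 700, budget = 5, master_seed = 42)
  r3 <- run_setting(s, cfg2, artifacts = art)
  expect_identical(r1$coefficients, r3$coefficients)
  expect_identical(r1$hyperparameters, r3$hyperparameters)
})

test_that("summaries use percentile intervals over repetitions", {
  df <- data.frame(setting = "S", method = "LR", repetition = 1:100,
                   metric = "auc", value = as.numeric(1:100))
  sm <- summarize_results(df)
  expect_equal(sm$mean, 50.5)
  expect_equal(sm$lower, unname(quantile(1:100, 0.025)))  # 3.475
  expect_equal(sm$upper, unname(quantile(1:100, 0.975)))  # 98.525
  expect_true(sm$lower <= median(df$value) && median(df$value) <= sm$upper)

  # constant metric: degenerate interval at the mean
  dfc <- data.frame(setting = "S", method = "LR", repetition = 1:10,
                    metric = "auc", value = rep(0.7, 10))
  smc <- summarize_results(dfc)
  expect_identical(c(smc$lower, smc$mean, smc$upper), rep(0.7, 3))
})

test_that("collinearity destabilizes maximum-likelihood predictor selection", {
  # paired low/high-collinearity versions of the small predictor set; the
  # sign-stability of plain logistic regression should drop under high
  # collinearity for nearly every master seed
  s_lo <- tiny_setting("T_lo", target_vif = 5, seed = 11)
  s_hi <- tiny_setting("T_hi", target_vif = 43, seed = 11,
                       collinearity = "high")
  art_lo <- build_setting_artifacts(s_lo, gt_mode = "draw")
  art_hi <- list(setting = s_hi,
                 corr = calibrate_collinearity(
                   build_block_correlation(s_hi$block_structure),
                   43, bs = s_hi$block_structure),
                 truth = art_lo$truth)  # same ground truth, new correlation
  art_hi$truth$intercept <- calibrate_intercept(art_hi$truth, art_hi$corr,
                                                s_hi$prevalence, mc_n = 100000,
                                                seed = 3)
  wins <- 0
  for (ms in 1:10) {
    cfg <- function(s) study_config(settings = list(s), methods = "LR",
                                    n_rep = 25, n_val = 200, master_seed = ms)
    m_lo <- run_setting(s_lo, cfg(s_lo), artifacts = art_lo)
    m_hi <- run_setting(s_hi, cfg(s_hi), artifacts = art_hi)
    mj <- function(r) r$results$value[r$results$metric == "mjics"]
    if (mj(m_hi) < mj(m_lo)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("repeated cross-validation mode analyzes observed data end to end", {
  # synthetic stand-in cohort: 740 records so stratified 5-fold training
  # parts have exactly 592 records
  s <- tiny_setting()
  art <- build_setting_artifacts(s, gt_mode = "draw")
  coh <- simulate_dataset(s, art$truth, art$corr, 740, seed = 88)
  # pad events to a multiple of 5 for exact stratified folds
  ev <- sum(coh$y)
  flip <- (ev %% 5)
  if (flip) coh$y[which(coh$y == 1)[seq_len(flip)]] <- 0L
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(coh, f)

  fold <- collinsim:::stratified_folds(coh$y, 5, seed = 1)
  expect_true(all(table(fold) == 148))  # train parts of 740 - 148 = 592

  cfg <- study_config(settings = list(s), methods = "LR", n_rep = 2,
                      budget = 5, master_seed = 9)
  res <- run_real_data_mode(f, "y", cfg)
  df <- res$results
  # 2 repeats x 5 folds of each per-fold metric; no MAE without ground truth
  expect_identical(sum(df$metric == "auc"), 10L)
  expect_false(any(df$metric %in% c("mae", "mse")))
  expect_identical(sum(df$metric == "mjics"), 1L)

  res2 <- run_real_data_mode(f, "y", cfg)
  expect_identical(res$results, res2$results)

  bad <- data.frame(x1 = rnorm(30), y = rnorm(30))
  fb <- tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(run_real_data_mode(fb, "y", cfg), "binary")
})

test_that("figure files are written and missing panels are skipped", {
  s <- tiny_setting()
  art <- build_setting_artifacts(s, gt_mode = "draw")
  cfg <- study_config(settings = list(s), methods = c("LR", "Ridge"),
                      n_rep = 2, n_val = 300, budget = 5, master_seed = 2)
  res <- run_setting(s, cfg, artifacts = art)
  out <- tempfile("figs")
  paths <- make_figures(res, out, settings = list(T = s))
  expect_true(length(paths) >= 3)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))

  # results lacking the stability metric: that panel skipped with a warning
  res2 <- res
  res2$results <- res2$results[res2$results$metric != "mjics", ]
  expect_warning(make_figures(res2, tempfile("figs2"),
                              settings = list(T = s)), "mjics")

  # calibration overlay from per-repetition curves
  pi <- withr::with_seed(1, runif(500, 0.05, 0.9))
  y <- withr::with_seed(2, rbinom(500, 1, pi))
  curves <- list(calibration_curve(y, pi), calibration_curve(y, pi^1.1))
  fcal <- file.path(out, "cal.png")
  plot_calibration_overlay(curves, pooled = curves[[1]], path = fcal)
  expect_true(file.size(fcal) > 0)
})

test_that("child seeds are stable, bounded, and stream-separating", {
  a <- child_seed(42, 1, 2, 3)
  expect_identical(a, child_seed(42, 1, 2, 3))
  expect_true(a >= 0 && a < 2^31 - 1)
  expect_false(child_seed(42, 1, 2, 3) == child_seed(42, 1, 2, 4))
  expect_false(child_seed(42, 1, 2, 3) == child_seed(42, 1, 3, 2))
  expect_false(child_seed(42, 1) == child_seed(43, 1))
})
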