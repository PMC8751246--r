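test_that("standardization centers, scales, and transfers to validation data", {
  fx <- make_fixture(n = 120, p = 4)
  expect_equal(unname(colMeans(fx$std$X)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(fx$std$X, 2, sd)), rep(1, 4), tolerance = 1e-10)

  # already standardized input: transform is the identity
  st2 <- standardize(fx$std)
  expect_equal(unname(st2$transform$means), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(st2$transform$sds), rep(1, 4), tolerance = 1e-10)

  # explicit location/scale column
  X <- cbind(a = rnorm(50, 5, 2), b = rnorm(50))
  st <- standardize(sim_dataset(X, rbinom(50, 1, 0.5)))
  expect_equal(mean(st$data$X[, 1]), 0, tolerance = 1e-10)
  expect_equal(sd(st$data$X[, 1]), 1, tolerance = 1e-10)

  # validation data transformed with train parameters keeps its own shift
  val <- matrix(rnorm(40, mean = 2), 10, 4)
  vs <- apply_standardization(fx$transform, val)
  expect_equal(vs, sweep(sweep(val, 2, fx$transform$means), 2,
                         fx$transform$sds, "/"))
  expect_gt(max(abs(colMeans(vs))), 0.5)

  Xc <- cbind(rnorm(30), rep(3, 30))
  colnames(Xc) <- c("good", "flat")
  expect_error(standardize(sim_dataset(Xc, rbinom(30, 1, 0.5))), "flat")
})

test_that("negative log-likelihood matches hand computation", {
  # perfect predictions: zero up to clipping
  expect_equal(negative_log_likelihood(40, c(80), matrix(c(1, 1), 2, 1),
                                       c(1, 1)), 0, tolerance = 1e-9)
  # null model: log 2 per record
  expect_equal(negative_log_likelihood(0, c(0, 0), matrix(rnorm(8), 4, 2),
                                       c(1, 0, 1, 0)), log(2))
  # 4-record worked instance, summed by explicit per-record arithmetic
  X <- matrix(c(1, -1, 0.5, 2), 4, 1)
  y <- c(1, 0, 0, 1)
  b0 <- 0.3; b1 <- -0.7
  pi <- 1 / (1 + exp(-(b0 + b1 * X[, 1])))
  by_hand <- -(log(pi[1]) + log(1 - pi[2]) + log(1 - pi[3]) + log(pi[4])) / 4
  expect_equal(negative_log_likelihood(b0, b1, X, y), by_hand,
               tolerance = 1e-12)
})

test_that("penalized fits agree with their limiting and oracle counterparts", {
  fx <- make_fixture(n = 200, p = 5, seed = 7)
  lr <- fit("LR", fx$std)
  expect_true(lr$converged)

  # Ridge with zero penalty: identical objective to LR
  r0 <- fit("Ridge", fx$std, hyperparameters(lambda_l2 = 0))
  expect_lt(max(abs(r0$coefficients - lr$coefficients)), 1e-4)

  # total shrinkage: exact zeros and the marginal log-odds intercept
  lbig <- fit("Lasso", fx$std, hyperparameters(lambda_l1 = 1e6))
  expect_identical(unname(lbig$coefficients), rep(0, 5))
  expect_equal(lbig$intercept, qlogis(mean(fx$std$y)), tolerance = 1e-3)

  # coordinate-descent oracle (glmnet) on a 200-record fixture, both at
  # moderate and selection-inducing penalty; penalty scale maps as lambda/n
  skip_if_not_installed("glmnet")
  for (lam in c(4, 40)) {
    mine <- fit("Lasso", fx$std, hyperparameters(lambda_l1 = lam))
    or <- glmnet::glmnet(fx$std$X, fx$std$y, family = "binomial", alpha = 1,
                         lambda = lam / 200, standardize = FALSE,
                         thresh = 1e-14)
    expect_lt(max(abs(c(mine$intercept, mine$coefficients) -
                      as.numeric(coef(or)))), 1e-3)
  }
  en <- fit("ElasticNet", fx$std, hyperparameters(lambda_l1 = 4,
                                                  lambda_l2 = 4))
  expect_true(en$converged)
})

test_that("non-negativity projection is exact and inactive constraints vanish", {
  fx <- make_fixture(n = 300, p = 5, beta = c(0.8, 0.6, 0.4, 0.3, -0.7),
                     seed = 9)
  lr <- fit("LR", fx$std)
  # constraints on truly positive coefficients are inactive: LR_NN == LR
  mask_inactive <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  stopifnot(all(lr$coefficients[mask_inactive] > 0))
  nn <- fit("LR_NN", fx$std, nonneg_mask = mask_inactive)
  expect_lt(max(abs(nn$coefficients - lr$coefficients)), 1e-4)

  # an active constraint clamps exactly at zero
  mask_active <- c(rep(FALSE, 4), TRUE)
  nn2 <- fit("LR_NN", fx$std, nonneg_mask = mask_active)
  expect_identical(unname(nn2$coefficients[5]), 0)
  expect_true(all(nn2$coefficients[mask_active] >= 0))
})

test_that("dropout reduces to LR without masking and is seed-reproducible", {
  fx <- make_fixture(n = 250, p = 4, seed = 13)
  lr <- fit("LR", fx$std)
  d0 <- fit("Dropout", fx$std, hyperparameters(delta = 0), seed = 3)
  expect_lt(max(abs(d0$coefficients - lr$coefficients)), 1e-4)

  d1 <- fit("Dropout", fx$std, hyperparameters(delta = 0.4), seed = 5)
  d2 <- fit("Dropout", fx$std, hyperparameters(delta = 0.4), seed = 5)
  expect_identical(d1$coefficients, d2$coefficients)
  d3 <- fit("Dropout", fx$std, hyperparameters(delta = 0.4), seed = 6)
  expect_false(identical(d1$coefficients, d3$coefficients))
  # masking shrinks towards the mean model relative to LR
  expect_lt(sum(d1$coefficients^2), sum(lr$coefficients^2) + 1e-8)
})

test_that("the tracked objective is non-increasing for deterministic methods", {
  fx <- make_fixture(n = 150, p = 4, seed = 21)
  cases <- list(list("LR", hyperparameters()),
                list("Ridge", hyperparameters(lambda_l2 = 3)),
                list("Lasso", hyperparameters(lambda_l1 = 3)),
                list("ElasticNet", hyperparameters(lambda_l1 = 2,
                                                   lambda_l2 = 2)))
  for (cs in cases) {
    m <- fit(cs[[1]], fx$std, cs[[2]], trace = TRUE)
    tr <- attr(m, "objective_trace")
    expect_true(all(diff(tr) <= 1e-12), label = paste(cs[[1]], "monotone"))
  }
  nn <- fit("LR_NN", fx$std, nonneg_mask = c(TRUE, TRUE, FALSE, FALSE),
            trace = TRUE)
  expect_true(all(diff(attr(nn, "objective_trace")) <= 1e-12))
})

test_that("shrinkage and support behave monotonically in the penalty", {
  fx <- make_fixture(n = 200, p = 5, seed = 31)
  l2_grid <- c(0.1, 1, 10, 100, 1000)
  norms <- vapply(l2_grid, function(l)
    sqrt(sum(fit("Ridge", fx$std, hyperparameters(lambda_l2 = l))$coefficients^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))

  l1_grid <- c(0.1, 1, 5, 20, 100, 1000)
  supports <- lapply(l1_grid, function(l)
    which(fit("Lasso", fx$std, hyperparameters(lambda_l1 = l))$coefficients != 0))
  sizes <- lengths(supports)
  expect_true(all(diff(sizes) <= 0))
})

test_that("ridge groups duplicated predictors", {
  n <- 200
  z <- withr::with_seed(5, rnorm(n))
  X <- cbind(z, z + rnorm(n, 0, 1e-6), withr::with_seed(6, rnorm(n)))
  colnames(X) <- c("x1", "x2", "x3")
  y <- withr::with_seed(7, rbinom(n, 1, plogis(0.8 * z)))
  st <- standardize(sim_dataset(X, y))
  m <- fit("Ridge", st$data, hyperparameters(lambda_l2 = 5))
  expect_lt(abs(m$coefficients[1] - m$coefficients[2]), 1e-3)
})

test_that("maximum likelihood recovers the generating coefficients at large n", {
  s <- tiny_setting()
  art <- build_setting_artifacts(s, gt_mode = "draw")
  big <- simulate_dataset(s, art$truth, art$corr, 50000, seed = 17)
  st <- standardize(big)
  m <- fit("LR", st$data)
  expect_lt(max(abs(m$coefficients - art$truth$coefficients)), 0.05)
})

test_that("predicted risks follow the logistic form and validate dimensions", {
  m <- collinsim:::new_fitted_model("LR", 0, c(x1 = 0, x2 = 0),
                                    hyperparameters(), TRUE, 1L)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(unname(predict_risk(m, X)), rep(0.5, 5))
  m$intercept <- qlogis(0.27)
  expect_equal(unname(predict_risk(m, X)), rep(0.27, 5))

  # 3-record worked instance by hand
  m2 <- collinsim:::new_fitted_model("LR", 0.2, c(x1 = 1, x2 = -0.5),
                                     hyperparameters(), TRUE, 1L)
  X3 <- matrix(c(1, 0, -1, 2, 0.5, 0), 3, 2)
  expect_equal(unname(predict_risk(m2, X3)),
               1 / (1 + exp(-(0.2 + X3[, 1] - 0.5 * X3[, 2]))))
  expect_error(predict_risk(m2, matrix(0, 2, 3)), "columns")
  expect_true(all(predict_risk(m2, X3) > 0 & predict_risk(m2, X3) < 1))
})

test_that("models round-trip through JSON with their standardization", {
  fx <- make_fixture(n = 100, p = 3, seed = 3)
  m <- fit("Ridge", fx$std, hyperparameters(lambda_l2 = 2))
  f <- tempfile(fileext = ".json")
  model_to_json(m, fx$transform, f)
  back <- model_from_json(f)
  expect_equal(back$model$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$model$intercept, m$intercept, tolerance = 1e-12)
  expect_identical(back$model$method, "Ridge")
  expect_equal(unlist(back$transform$means), unname(fx$transform$means),
               tolerance = 1e-12, ignore_attr = TRUE)

  # raw-scale export: predictions agree on original-scale data
  raw <- raw_scale_coefficients(m, fx$transform)
  eta_raw <- raw$intercept + drop(fx$raw$X %*% raw$coefficients)
  eta_std <- m$intercept + drop(fx$std$X %*% m$coefficients)
  expect_equal(eta_raw, eta_std, tolerance = 1e-10)
})
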