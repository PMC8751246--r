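#' Search space for a method's hyperparameters
#'
#' Penalty weights (`lambda_l1`, `lambda_l2`, `lambda_lae`) are searched
#' log-uniformly on `[1e-5, 1e3]`, the dropout ratio uniformly on `[0, 0.9]`,
#' and component counts uniformly on the integers `1..p`.
#'
#' @param method method label.
#' @param p number of predictors.
#' @return named list of parameter domains (empty for LR and LR_NN).
#' @export
search_space <- function(method, p) {
  method <- match.arg(method, METHOD_LABELS)
  lo_lambda <- 1e-5; hi_lambda <- 1e3
  logdom <- function() list(type = "log", lower = lo_lambda, upper = hi_lambda)
  switch(method,
    LR = list(),
    LR_NN = list(),
    Lasso = list(lambda_l1 = logdom()),
    Ridge = list(lambda_l2 = logdom()),
    ElasticNet = list(lambda_l1 = logdom(), lambda_l2 = logdom()),
    Dropout = list(delta = list(type = "unif", lower = 0, upper = 0.9)),
    PCLR = list(d_pca = list(type = "int", lower = 1, upper = p)),
    LAELR = list(d_lae = list(type = "int", lower = 1, upper = p),
                 lambda_lae = logdom()))
}

#' @keywords internal
unit_to_hp <- function(u, space) {
  vals <- mapply(function(ui, dom) {
    switch(dom$type,
           log = exp(log(dom$lower) + ui * (log(dom$upper) - log(dom$lower))),
           unif = dom$lower + ui * (dom$upper - dom$lower),
           int = as.integer(round(dom$lower + ui * (dom$upper - dom$lower))))
  }, as.list(u), space, SIMPLIFY = FALSE)
  names(vals) <- names(space)
  do.call(hyperparameters, vals)
}

#' @keywords internal
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated held-out log-likelihood of a hyperparameter set
#'
#' Mean over k stratified folds of the held-out mean log-likelihood of the
#' model fitted on the fold's training part, with standardization refit on
#' each training part. Larger is better.
#'
#' @param method method label.
#' @param hp a [hyperparameters()].
#' @param data development [sim_dataset()] (unstandardized).
#' @param k number of folds (default 3).
#' @param seed seed for the fold split and stochastic fits.
#' @param nonneg_mask passed to [fit()] for LR_NN.
#' @return scalar mean held-out log-likelihood (per record).
#' @export
cv_log_likelihood <- function(method, hp, data, k = 3, seed = 1L,
                              nonneg_mask = NULL) {
  stopifnot(inherits(data, "sim_dataset"), k >= 2)
  fold <- stratified_folds(data$y, k, child_seed(seed, 999L))
  ll <- numeric(k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    if (length(unique(data$y[tr_idx])) < 2 ||
        length(unique(data$y[te_idx])) < 2)
      stopf("single-class fold after stratification (k too large?)")
    tr <- sim_dataset(data$X[tr_idx, , drop = FALSE], data$y[tr_idx])
    st <- standardize(tr)
    model <- fit(method, st$data, hp, seed = child_seed(seed, f, 17L),
                 nonneg_mask = nonneg_mask)
    Xte <- apply_standardization(st$transform, data$X[te_idx, , drop = FALSE])
    ll[f] <- -negative_log_likelihood(model$intercept, model$coefficients,
                                      Xte, data$y[te_idx])
  }
  mean(ll)
}

# --- minimal Gaussian-process surrogate (squared-exponential kernel) --------

#' @keywords internal
gp_fit <- function(U, z, lengthscale = 0.25, nugget = 1e-6) {
  mu <- mean(z); sdz <- stats::sd(z)
  if (!is.finite(sdz) || sdz < 1e-12) sdz <- 1
  zs <- (z - mu) / sdz
  D2 <- as.matrix(stats::dist(U))^2
  K <- exp(-0.5 * D2 / lengthscale^2) + diag(nugget, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), zs))
  list(U = U, L = L, alpha = alpha, mu = mu, sdz = sdz,
       lengthscale = lengthscale)
}

#' @keywords internal
gp_predict <- function(gpm, Unew) {
  d2 <- outer(rowSums(Unew^2), rowSums(gpm$U^2), "+") -
    2 * Unew %*% t(gpm$U)
  Ks <- exp(-0.5 * pmax(d2, 0) / gpm$lengthscale^2)
  mean_s <- drop(Ks %*% gpm$alpha)
  v <- forwardsolve(t(gpm$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gpm$mu + gpm$sdz * mean_s, sd = gpm$sdz * sqrt(var_s))
}

#' @keywords internal
expected_improvement <- function(pred, best) {
  imp <- pred$mean - best
  zz <- imp / pred$sd
  imp * stats::pnorm(zz) + pred$sd * stats::dnorm(zz)
}

#' Tune a method's hyperparameters
#'
#' Sequential model-based (Bayesian) optimization of the cross-validated
#' held-out log-likelihood: 5 space-filling (maximin Latin hypercube)
#' evaluations followed by Gaussian-process expected-improvement proposals,
#' all on the unit hypercube of the method's [search_space()]. Deterministic
#' under a fixed seed, with per-iteration seeding so that a longer budget
#' extends (never alters) a shorter run's evaluation sequence. Methods without
#' hyperparameters (LR, LR_NN) return an empty result without evaluation.
#'
#' @param method method label.
#' @param data development [sim_dataset()] (unstandardized); tuning never
#'   sees validation data.
#' @param space optional [search_space()] override.
#' @param budget total number of criterion evaluations (>= 5; default 30).
#' @param seed integer seed.
#' @param k folds for [cv_log_likelihood()].
#' @param optimizer `"bo"` (default) or `"random"` (pure random search behind
#'   the same interface).
#' @param nonneg_mask passed through to the fits (LR_NN).
#' @return a `tuning_result`: list with `best` ([hyperparameters()]),
#'   `history` (data.frame of evaluations and criteria), `budget_used`,
#'   `seed`.
#' @export
tune <- function(method, data, space = NULL, budget = 30, seed = 1L, k = 3,
                 optimizer = c("bo", "random"), nonneg_mask = NULL) {
  method <- match.arg(method, METHOD_LABELS)
  optimizer <- match.arg(optimizer)
  space <- space %||% search_space(method, ncol(data$X))
  if (length(space) == 0) {
    return(structure(list(best = hyperparameters(),
                          history = data.frame(criterion = numeric(0)),
                          budget_used = 0L, seed = seed),
                     class = "tuning_result"))
  }
  if (budget < 5) stopf("tuning budget must be >= 5")
  d <- length(space)

  U <- matrix(NA_real_, budget, d)
  crit <- numeric(budget)
  n_init <- 5L
  U[seq_len(n_init), ] <- withr::with_seed(child_seed(seed, 0L),
                                           lhs::maximinLHS(n_init, d))
  eval_point <- function(u, t) {
    hp <- unit_to_hp(u, space)
    cv_log_likelihood(method, hp, data, k = k,
                      seed = child_seed(seed, 555L),
                      nonneg_mask = nonneg_mask)
  }
  for (t in seq_len(n_init)) crit[t] <- eval_point(U[t, ], t)

  if (budget > n_init) {
    for (t in (n_init + 1L):budget) {
      u_new <- withr::with_seed(child_seed(seed, t), {
        cand <- matrix(stats::runif(200 * d), 200, d)
        if (optimizer == "random") {
          cand[1, , drop = TRUE]
        } else {
          done <- seq_len(t - 1L)
          # local refinements around the incumbent
          best_u <- U[done[which.max(crit[done])], ]
          local <- matrix(rep(best_u, each = 56), 56, d, byrow = FALSE)
          local <- pmin(pmax(local + matrix(stats::rnorm(56 * d, 0, 0.05),
                                            56, d), 0), 1)
          cand <- rbind(cand, local)
          gpm <- gp_fit(U[done, , drop = FALSE], crit[done])
          ei <- expected_improvement(gp_predict(gpm, cand), max(crit[done]))
          cand[which.max(ei), , drop = TRUE]
        }
      })
      U[t, ] <- u_new
      crit[t] <- eval_point(u_new, t)
    }
  }

  hist_hp <- do.call(rbind, lapply(seq_len(budget), function(t)
    as.data.frame(unclass(unit_to_hp(U[t, ], space)))))
  history <- cbind(hist_hp, criterion = crit)
  best_idx <- which.max(crit)
  structure(list(best = unit_to_hp(U[best_idx, ], space),
                 history = history, budget_used = as.integer(budget),
                 seed = seed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  if (x$budget_used == 0) {
    cat("<tuning_result> no hyperparameters to tune\n")
  } else {
    hp <- unlist(x$best)
    cat(sprintf("<tuning_result> %d evaluations; best criterion %.4f at %s\n",
                x$budget_used, max(x$history$criterion),
                paste(names(hp), signif(hp, 3), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Write a tuning history as CSV
#'
#' @param result a `tuning_result`.
#' @param method method label recorded in the file.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tuning_csv <- function(result, method, path) {
  h <- result$history
  if (nrow(h)) h <- cbind(method = method, h)
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
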