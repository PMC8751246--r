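# Shared fixtures, generated in code at test time.

# equicorrelated p x p correlation matrix
equicorr <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}

# correlated logistic-model data on a known ground truth; returns the raw
# and standardized datasets plus the generating parameters
make_fixture <- function(n = 300, p = 5, rho = 0.4,
                         beta = NULL, intercept = -0.5, seed = 42) {
  if (is.null(beta)) beta <- c(0.8, -0.5, 0.3, rep(0, p - 3))
  R <- equicorr(p, rho)
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p)) %*% chol(R)
  colnames(X) <- paste0("x", seq_len(p))
  pi <- stats::plogis(intercept + drop(X %*% beta))
  y <- withr::with_seed(seed + 1, stats::rbinom(n, 1, pi))
  ds <- sim_dataset(X, y)
  st <- standardize(ds)
  list(raw = ds, std = st$data, transform = st$transform,
       beta = beta, intercept = intercept, R = R)
}

# small setting spec for cheap end-to-end harness tests
tiny_setting <- function(name = "T", target_vif = 5, seed = 11,
                         collinearity = "low") {
  bs <- block_structure(c(2, 2), within_block_r = 0.8,
                        between_block_r = 0.2, n_clinical = 3)
  setting_spec(name, "xerostomia", bs, target_median_vif = target_vif,
               target_events = 161, n_dev = 592, n_val = 1000,
               collinearity = collinearity, seed = seed)
}

# independent enumeration oracle for the sign-Jaccard index: explicit
# (index, sign) set construction with set operations
jaccard_oracle <- function(a, b) {
  sgn3 <- function(x) ifelse(x > 0.01, 1L, ifelse(x < -0.01, -1L, 0L))
  set_of <- function(v) {
    s <- sgn3(v)
    paste0(which(s != 0), ":", s[s != 0])
  }
  A <- set_of(a); B <- set_of(b)
  if (length(union(A, B)) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

mjics_oracle <- function(vecs) {
  m <- length(vecs)
  vals <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    vals <- c(vals, jaccard_oracle(vecs[[i]], vecs[[j]]))
  mean(vals)
}
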