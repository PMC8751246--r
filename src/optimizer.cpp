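// First-order optimization core shared by all logistic-model variants.
//
// Deterministic objectives (maximum likelihood, ridge, lasso, elastic net,
// non-negativity-projected ML, and the second stage of PCLR) are minimized by
// monotone proximal gradient descent with Barzilai-Borwein steps and
// backtracking; the l1 term and the non-negativity constraint live in the
// proximal map (exact zeros, exact projection). Dropout uses constant-step
// proximal SGD with per-iteration predictor masking. The linear-autoencoder
// model uses the same BB+backtracking scheme on its joint (nonconvex)
// objective. Objectives are per-record: mean NLL + (l1*|b|_1 + l2*|b|^2)/n.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// mean negative log-likelihood of a logistic model with linear predictor eta
static double mean_nll(const vec& eta, const vec& y) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    s += softplus(eta[i]) - y[i] * eta[i];
  return s / eta.n_elem;
}

// proximal map of (l1n * |x|_1 + indicator(x_j >= 0 for masked j)) at step t
static vec prox_step(const vec& z, double t, double l1n,
                     const uvec& nonneg) {
  vec out = z;
  const double thr = t * l1n;
  if (thr > 0.0) {
    for (uword j = 0; j < out.n_elem; ++j) {
      if (out[j] > thr) out[j] -= thr;
      else if (out[j] < -thr) out[j] += thr;
      else out[j] = 0.0;
    }
  }
  for (uword k = 0; k < nonneg.n_elem; ++k) {
    uword j = nonneg[k];
    if (out[j] < 0.0) out[j] = 0.0;
  }
  return out;
}

// largest eigenvalue of X'X (exact; p is small in this package)
static double xtx_eigmax(const mat& X) {
  mat S = X.t() * X;
  vec ev = eig_sym(S);
  return ev.max();
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_glm(const arma::mat& X, const arma::vec& y,
                       double lambda1, double lambda2, double delta,
                       const arma::uvec& nonneg_idx0,
                       int seed, int max_iter, double tol, int patience,
                       bool trace) {
  const uword n = X.n_rows, p = X.n_cols;
  const double l1n = lambda1 / n;
  const double l2n = lambda2 / n;

  double b0 = std::log(std::max(mean(y), 1e-6) /
                       std::max(1.0 - mean(y), 1e-6));
  vec beta(p, fill::zeros);
  std::vector<double> obj_trace;

  auto full_objective = [&](double b0_, const vec& beta_) {
    vec eta = b0_ + X * beta_;
    return mean_nll(eta, y) + l2n * dot(beta_, beta_) +
           l1n * norm(beta_, 1);
  };

  const double L0 = xtx_eigmax(X) / (4.0 * n) + 2.0 * l2n + 0.25;

  bool converged = false;
  int iter = 0;

  if (delta <= 0.0) {
    // deterministic: proximal gradient with BB step + backtracking
    double t = 1.0 / L0;
    vec g_prev(p, fill::zeros);
    double g0_prev = 0.0;
    vec beta_prev = beta;
    double b0_prev = b0;
    bool have_prev = false;
    int calm = 0;

    double phi = full_objective(b0, beta);
    if (trace) obj_trace.push_back(phi);

    for (iter = 1; iter <= max_iter; ++iter) {
      vec eta = b0 + X * beta;
      double f = mean_nll(eta, y) + l2n * dot(beta, beta);
      vec pi = 1.0 / (1.0 + exp(-eta));
      vec r = (pi - y) / n;
      double g0 = accu(r);
      vec g = X.t() * r + 2.0 * l2n * beta;

      if (have_prev) {
        vec s = join_cols(vec{b0 - b0_prev}, beta - beta_prev);
        vec dg = join_cols(vec{g0 - g0_prev}, g - g_prev);
        double sy = dot(s, dg);
        if (sy > 1e-16) {
          t = dot(s, s) / sy;
          t = std::min(std::max(t, 1e-12), 1e8);
        }
      }
      b0_prev = b0; beta_prev = beta; g0_prev = g0; g_prev = g;
      have_prev = true;

      double f_new = 0.0, b0_new = 0.0, phi_new = 0.0;
      vec beta_new;
      for (int bt = 0; bt < 80; ++bt) {
        b0_new = b0 - t * g0;
        beta_new = prox_step(beta - t * g, t, l1n, nonneg_idx0);
        vec eta_new = b0_new + X * beta_new;
        f_new = mean_nll(eta_new, y) + l2n * dot(beta_new, beta_new);
        double db0 = b0_new - b0;
        vec db = beta_new - beta;
        double quad = f + g0 * db0 + dot(g, db) +
                      (db0 * db0 + dot(db, db)) / (2.0 * t);
        if (f_new <= quad + 1e-15) break;
        t *= 0.5;
      }
      b0 = b0_new; beta = beta_new; f = f_new;
      phi_new = f + l1n * norm(beta, 1);
      if (trace) obj_trace.push_back(phi_new);

      double rel = std::fabs(phi - phi_new) / std::max(1.0, std::fabs(phi));
      phi = phi_new;
      calm = (rel < tol) ? calm + 1 : 0;
      if (calm >= patience) { converged = true; break; }
    }
  } else {
    // dropout: constant-step proximal SGD with per-iteration column masking
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    const double keep = 1.0 - delta;
    const double t = keep * keep / L0;  // step for the 1/(1-delta)-scaled data
    const int window = 200;
    double win_sum = 0.0, win_prev = datum::inf;
    vec ms(p);

    for (iter = 1; iter <= max_iter; ++iter) {
      for (uword j = 0; j < p; ++j)
        ms[j] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      vec beta_eff = beta % ms;
      vec eta = b0 + X * beta_eff;
      vec pi = 1.0 / (1.0 + exp(-eta));
      vec r = (pi - y) / n;
      double g0 = accu(r);
      vec g = (X.t() * r) % ms + 2.0 * l2n * beta;
      b0 -= t * g0;
      beta = prox_step(beta - t * g, t, l1n, nonneg_idx0);

      double phi_m = mean_nll(eta, y) + l2n * dot(beta, beta) +
                     l1n * norm(beta, 1);
      if (trace) obj_trace.push_back(phi_m);
      win_sum += phi_m;
      if (iter % window == 0) {
        double win_mean = win_sum / window;
        // plateau: no material improvement over the previous window
        if (std::isfinite(win_prev) &&
            win_mean >= win_prev - 1e-4 * std::max(1.0, std::fabs(win_prev))) {
          converged = true; break;
        }
        win_prev = win_mean;
        win_sum = 0.0;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("intercept") = b0,
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iterations") = std::min(iter, max_iter),
      Rcpp::Named("objective_trace") = obj_trace);
}

// Tied linear autoencoder + logistic head: the decoder is the encoder
// transpose, which removes the re-parametrization flat directions an untied
// pair has on perfectly collinear predictors (only the sum of encoder rows
// would be identified), keeping back-projected coefficients well defined.
// [[Rcpp::export]]
Rcpp::List cpp_fit_laelr(const arma::mat& X, const arma::vec& y,
                         int d, double lambda_lae, int seed,
                         double init_scale, int max_iter, double tol,
                         int patience, bool trace) {
  const uword n = X.n_rows, p = X.n_cols;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm01(0.0, 1.0);

  mat A(p, d);
  vec w(d);
  for (auto& v : A) v = init_scale * norm01(rng);
  for (auto& v : w) v = init_scale * norm01(rng);
  double b = std::log(std::max(mean(y), 1e-6) /
                      std::max(1.0 - mean(y), 1e-6));

  const double rec_w = lambda_lae / (double(n) * double(p));
  std::vector<double> obj_trace;

  auto objective = [&](const mat& A_, const vec& w_, double b_) {
    mat S = X * A_;
    vec eta = b_ + S * w_;
    mat R = X - S * A_.t();
    return mean_nll(eta, y) + rec_w * accu(R % R);
  };

  // gradient of the joint objective; for the tied reconstruction term
  // grad_A ||X - X A A'||^2 = -2 (G + G') A with G = X'R
  auto gradient = [&](const mat& A_, const vec& w_, double b_,
                      mat& gA, vec& gw, double& gb) {
    mat S = X * A_;
    vec eta = b_ + S * w_;
    vec pi = 1.0 / (1.0 + exp(-eta));
    vec r = (pi - y) / n;
    gb = accu(r);
    gw = S.t() * r;
    gA = X.t() * r * w_.t();
    mat R = X - S * A_.t();
    mat G = X.t() * R;
    gA += (-2.0 * rec_w) * ((G + G.t()) * A_);
  };

  double phi = objective(A, w, b);
  if (trace) obj_trace.push_back(phi);

  double t = 1e-2 / (1.0 + lambda_lae);
  mat gA(p, d);
  vec gw(d);
  double gb = 0.0;
  mat gA_prev, A_prev;
  vec gw_prev, w_prev;
  double gb_prev = 0.0, b_prev = 0.0;
  bool have_prev = false, converged = false;
  int calm = 0, iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    gradient(A, w, b, gA, gw, gb);
    if (have_prev) {
      double ss = accu(square(A - A_prev)) + accu(square(w - w_prev)) +
                  (b - b_prev) * (b - b_prev);
      double sy = accu((A - A_prev) % (gA - gA_prev)) +
                  dot(w - w_prev, gw - gw_prev) +
                  (b - b_prev) * (gb - gb_prev);
      if (sy > 1e-16) t = std::min(std::max(ss / sy, 1e-12), 1e6);
    }
    A_prev = A; w_prev = w; b_prev = b;
    gA_prev = gA; gw_prev = gw; gb_prev = gb;
    have_prev = true;

    double gnorm2 = accu(square(gA)) + dot(gw, gw) + gb * gb;
    double phi_new = phi;
    for (int bt = 0; bt < 80; ++bt) {
      mat A_new = A - t * gA;
      vec w_new = w - t * gw;
      double b_new = b - t * gb;
      phi_new = objective(A_new, w_new, b_new);
      if (phi_new <= phi - 0.5 * t * gnorm2 + 1e-15 || bt == 79) {
        A = A_new; w = w_new; b = b_new;
        break;
      }
      t *= 0.5;
    }
    if (trace) obj_trace.push_back(phi_new);
    double rel = std::fabs(phi - phi_new) / std::max(1.0, std::fabs(phi));
    phi = phi_new;
    calm = (rel < tol) ? calm + 1 : 0;
    if (calm >= patience) { converged = true; break; }
  }

  return Rcpp::List::create(
      Rcpp::Named("W_enc") = A,
      Rcpp::Named("W_dec") = A.t(),
      Rcpp::Named("w") = w,
      Rcpp::Named("intercept") = b,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iterations") = std::min(iter, max_iter),
      Rcpp::Named("objective_trace") = obj_trace);
}
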