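#include <Rcpp.h>
using namespace Rcpp;

// Binomial GLMM with one random intercept per word. The likelihood
// factorizes over words (single grouping factor), so each word needs one
// 1-D integral over its random effect u:
//
//   L_w = \int Binom(n_w | f_w, logit^{-1}(eta0_w + u)) dnorm(u; 0, sigma) du
//
// evaluated by adaptive Gauss-Hermite quadrature centred at the word's
// conditional mode (Laplace when a single node is used).

static inline double softplus(double x) {
  // log(1 + exp(x)), stable for large |x|
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

static inline double invlogit(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log Binom(n | f, invlogit(eta)) including the binomial coefficient
static inline double binom_logpmf(double n, double f, double eta,
                                  double lch) {
  return lch + n * eta - f * softplus(eta);
}

// Newton solve for the mode of
//   h(u) = log Binom(n | f, invlogit(eta0 + u)) - u^2 / (2 sigma^2)
// h is strictly concave in u, so undamped Newton with a step cap converges.
static inline void solve_mode(double n, double f, double eta0, double sigma,
                              double &u, double &neg_h2) {
  double inv_s2 = 1.0 / (sigma * sigma);
  u = 0.0;
  for (int it = 0; it < 100; ++it) {
    double p = invlogit(eta0 + u);
    double g = n - f * p - u * inv_s2;
    double h2 = f * p * (1.0 - p) + inv_s2;
    double step = g / h2;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    u += step;
    if (std::fabs(step) < 1e-12) break;
  }
  double p = invlogit(eta0 + u);
  neg_h2 = f * p * (1.0 - p) + inv_s2;
}

// [[Rcpp::export]]
NumericMatrix cpp_cond_modes(NumericVector n, NumericVector f,
                             NumericVector eta0, double sigma) {
  int W = n.size();
  NumericMatrix out(W, 2); // column 1: mode, column 2: curvature -h''(u*)
  if (sigma <= 0.0) {
    for (int w = 0; w < W; ++w) {
      out(w, 0) = 0.0;
      out(w, 1) = R_PosInf;
    }
    return out;
  }
  for (int w = 0; w < W; ++w) {
    double u, neg_h2;
    solve_mode(n[w], f[w], eta0[w], sigma, u, neg_h2);
    out(w, 0) = u;
    out(w, 1) = neg_h2;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_marginal_loglik(NumericVector n, NumericVector f,
                           NumericVector eta0, double sigma,
                           NumericVector qx, NumericVector qw) {
  int W = n.size();
  int K = qx.size();
  if (f.size() != W || eta0.size() != W) {
    stop("n, f, and eta0 must have equal length");
  }
  double ll = 0.0;

  if (sigma <= 0.0) {
    // degenerate prior: all u = 0
    for (int w = 0; w < W; ++w) {
      double lch = Rf_lchoose(f[w], n[w]);
      ll += binom_logpmf(n[w], f[w], eta0[w], lch);
    }
    return ll;
  }

  double log_sigma_norm = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  double inv_2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> lqw(K);
  for (int k = 0; k < K; ++k) lqw[k] = std::log(qw[k]) + qx[k] * qx[k];

  for (int w = 0; w < W; ++w) {
    double u, neg_h2;
    solve_mode(n[w], f[w], eta0[w], sigma, u, neg_h2);
    double s = 1.0 / std::sqrt(neg_h2);
    double lch = Rf_lchoose(f[w], n[w]);

    // log sum over nodes of qw_k exp(qx_k^2) g(u* + sqrt(2) s qx_k)
    double m = R_NegInf;
    std::vector<double> terms(K);
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * s * qx[k];
      double h = binom_logpmf(n[w], f[w], eta0[w] + uk, lch)
                 - uk * uk * inv_2s2 + log_sigma_norm;
      terms[k] = lqw[k] + h;
      if (terms[k] > m) m = terms[k];
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(terms[k] - m);
    ll += std::log(M_SQRT2 * s) + m + std::log(acc);
  }
  return ll;
}
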