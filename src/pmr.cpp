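// Core numerical routines: univariate penalized surrogate maximization
// (thresholding operators), minorize-maximization coordinate ascent for
// penalized GLMs, and the per-marker logistic likelihood-ratio scan.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

enum Family { LASSO = 0, ADAPTIVE = 1, LOGPEN = 2, NEG = 3, MCP = 4 };

// Penalty state decoded once from the R-side penalty_spec.
struct Penalty {
  int family;
  double lam;    // rate: slope of the penalty near the origin
  double shape;  // mcp gamma, log eta, neg shape
  arma::vec w;   // per-coordinate multipliers (adaptive lasso), else empty
  // NEG derivative/value tabulation on a b-grid (computed in R from the
  // parabolic-cylinder ratio); extended with the (2a+1)/b asymptote.
  arma::vec neg_b, neg_dp, neg_pv;
  double neg_c;
};

Penalty decode_penalty(const List &pen) {
  Penalty p;
  p.family = as<int>(pen["family_code"]);
  p.lam = as<double>(pen["rate"]);
  p.shape = as<double>(pen["shape"]);
  if (pen.containsElementNamed("weights") && !Rf_isNull(pen["weights"]))
    p.w = as<arma::vec>(pen["weights"]);
  if (p.family == NEG) {
    p.neg_b = as<arma::vec>(pen["neg_b"]);
    p.neg_dp = as<arma::vec>(pen["neg_dp"]);
    p.neg_pv = as<arma::vec>(pen["neg_pv"]);
    p.neg_c = as<double>(pen["neg_c"]);
  }
  return p;
}

// linear interpolation on the NEG grid; asymptotic extension beyond it
double neg_interp(const arma::vec &x, const arma::vec &y, double b) {
  const arma::uword n = x.n_elem;
  if (b <= x[0]) return y[0];
  if (b >= x[n - 1]) return arma::datum::nan;  // caller handles tail
  arma::uword hi = std::lower_bound(x.begin(), x.end(), b) - x.begin();
  arma::uword lo = hi - 1;
  double t = (b - x[lo]) / (x[hi] - x[lo]);
  return (1.0 - t) * y[lo] + t * y[hi];
}

// P(b) for b >= 0, on the log-likelihood scale
double penalty_value(double b, const Penalty &p, double w) {
  if (b <= 0.0) return 0.0;
  const double lam = p.lam * w;
  switch (p.family) {
    case LASSO:
    case ADAPTIVE:
      return lam * b;
    case MCP: {
      const double g = p.shape;
      return (b <= g * lam) ? lam * b - b * b / (2.0 * g)
                            : g * lam * lam / 2.0;
    }
    case LOGPEN: {
      const double eta = p.shape;
      return lam * std::log1p(b / eta) / std::log1p(1.0 / eta);
    }
    case NEG: {
      const double bmax = p.neg_b[p.neg_b.n_elem - 1];
      if (b < bmax) return neg_interp(p.neg_b, p.neg_pv, b) * lam;
      // derivative saturates to neg_c / b beyond the table
      return (p.neg_pv[p.neg_pv.n_elem - 1] +
              p.neg_c * std::log(b / bmax)) * lam;
    }
  }
  return NA_REAL;
}

// dP/db for b >= 0
double penalty_deriv(double b, const Penalty &p, double w) {
  const double lam = p.lam * w;
  switch (p.family) {
    case LASSO:
    case ADAPTIVE:
      return lam;
    case MCP:
      return std::max(lam - b / p.shape, 0.0);
    case LOGPEN: {
      const double eta = p.shape;
      return lam / (std::log1p(1.0 / eta) * (eta + b));
    }
    case NEG: {
      const double bmax = p.neg_b[p.neg_b.n_elem - 1];
      if (b < bmax) return neg_interp(p.neg_b, p.neg_dp, b) * lam;
      return lam * p.neg_c / b;
    }
  }
  return NA_REAL;
}

// surrogate f(b) = -(d/2)(b - az)^2 - P(b), b >= 0 with az = |z|
inline double surr(double b, double az, double d, const Penalty &p, double w) {
  const double r = b - az;
  return -0.5 * d * r * r - penalty_value(b, p, w);
}

// golden-section refinement of a bracketed interior maximum
double golden_max(double lo, double hi, double az, double d,
                  const Penalty &p, double w) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = surr(x1, az, d, p, w), f2 = surr(x2, az, d, p, w);
  for (int it = 0; it < 80 && (b - a) > 1e-11; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = surr(x2, az, d, p, w);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = surr(x1, az, d, p, w);
    }
  }
  return (f1 > f2) ? x1 : x2;
}

// argmax_b -(d/2)(b - z)^2 - P(|b|): the coordinate thresholding operator
double cd_update(double z, double d, const Penalty &p, double w) {
  if (d <= 0.0) return 0.0;
  const double az = std::fabs(z), sgn = (z >= 0.0) ? 1.0 : -1.0;
  if (az == 0.0) return 0.0;
  const double lam = p.lam * w;

  if (p.family == LASSO || p.family == ADAPTIVE)
    return sgn * std::max(az - lam / d, 0.0);

  const double f0 = -0.5 * d * az * az;  // surrogate value at b = 0

  if (p.family == MCP) {
    const double g = p.shape;
    double best_b = 0.0, best_f = f0;
    const double denom = 1.0 - 1.0 / (g * d);
    if (denom > 0.0) {
      double b1 = (az - lam / d) / denom;
      if (b1 > 0.0) {
        b1 = std::min(b1, g * lam);
        double f1 = surr(b1, az, d, p, w);
        if (f1 > best_f) { best_f = f1; best_b = b1; }
      }
    } else {
      // non-convex surrogate: boundary of the quadratic region
      double f1 = surr(g * lam, az, d, p, w);
      if (f1 > best_f) { best_f = f1; best_b = g * lam; }
    }
    if (az > g * lam) {  // plateau region: penalty constant, optimum at z
      double f2 = surr(az, az, d, p, w);
      if (f2 > best_f) { best_f = f2; best_b = az; }
    }
    return sgn * best_b;
  }

  if (p.family == LOGPEN) {
    // stationary points solve d(az - b)(eta + b) = c, a quadratic in b
    const double eta = p.shape;
    const double c = lam / std::log1p(1.0 / eta);
    double best_b = 0.0, best_f = f0;
    const double h = az - eta;
    const double disc = h * h + 4.0 * (az * eta - c / d);
    if (disc >= 0.0) {
      const double s = std::sqrt(disc);
      for (double b1 : {(h + s) / 2.0, (h - s) / 2.0}) {
        if (b1 > 0.0 && b1 <= az) {
          double f1 = surr(b1, az, d, p, w);
          if (f1 > best_f) { best_f = f1; best_b = b1; }
        }
      }
    }
    return sgn * best_b;
  }

  // NEG: safeguarded search — coarse grid over (0, az], golden refinement
  // around the best grid point, compared against b = 0.
  const int K = 64;
  double best_b = 0.0, best_f = f0;
  int best_i = -1;
  for (int i = 1; i <= K; ++i) {
    const double b1 = az * static_cast<double>(i) / K;
    const double f1 = surr(b1, az, d, p, w);
    if (f1 > best_f) { best_f = f1; best_b = b1; best_i = i; }
  }
  if (best_i >= 1) {
    const double lo = az * static_cast<double>(best_i - 1) / K;
    const double hi = az * static_cast<double>(std::min(best_i + 1, K)) / K;
    const double br = golden_max(lo, hi, az, d, p, w);
    if (surr(br, az, d, p, w) > best_f) best_b = br;
    if (surr(best_b, az, d, p, w) <= f0) best_b = 0.0;
  }
  return sgn * best_b;
}

inline double logistic_mu(double eta) {
  if (eta > 30.0) eta = 30.0;
  if (eta < -30.0) eta = -30.0;
  return 1.0 / (1.0 + std::exp(-eta));
}

double work_loglik(const arma::vec &y, const arma::vec &eta, int fam) {
  if (fam == 0) {  // linear: -RSS/2 working likelihood
    return -0.5 * arma::dot(y - eta, y - eta);
  }
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double e = std::min(std::max(eta[i], -30.0), 30.0);
    ll += y[i] * e - std::log1p(std::exp(e));
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
double cpp_penalty_value(double b, List pen, double w = 1.0) {
  Penalty p = decode_penalty(pen);
  return penalty_value(b, p, w);
}

// [[Rcpp::export]]
double cpp_penalty_deriv(double b, List pen, double w = 1.0) {
  Penalty p = decode_penalty(pen);
  return penalty_deriv(b, p, w);
}

// [[Rcpp::export]]
double cpp_cd_update(double z, double d, List pen, double w = 1.0) {
  Penalty p = decode_penalty(pen);
  return cd_update(z, d, p, w);
}

// Penalized objective ell(beta) - sum_j P(|beta_j|) for a full coefficient
// state (covariates unpenalized).
// [[Rcpp::export]]
double cpp_penalized_objective(const arma::mat &X, const arma::mat &C,
                               const arma::vec &y, int glm_family,
                               List pen, const arma::vec &beta,
                               const arma::vec &alpha) {
  Penalty p = decode_penalty(pen);
  arma::vec eta = C * alpha + X * beta;
  double obj = work_loglik(y, eta, glm_family);
  for (arma::uword j = 0; j < beta.n_elem; ++j) {
    double w = p.w.n_elem ? p.w[j] : 1.0;
    obj -= penalty_value(std::fabs(beta[j]), p, w);
  }
  return obj;
}

// MM coordinate ascent for the penalized GLM.
//   glm_family: 0 = linear (identity link, -RSS/2 working loglik),
//               1 = logistic.
//   order: 0-based marker update order.
// Covariates are updated unpenalized at the start of every sweep.
// Curvature bounds: d_j = sum x_ij^2 (linear) or sum x_ij^2 / 4 (logistic).
// [[Rcpp::export]]
List cpp_fit_pmle(const arma::mat &X, const arma::mat &C, const arma::vec &y,
                  int glm_family, List pen, const arma::uvec &order,
                  arma::vec beta, arma::vec alpha, double tol = 1e-5,
                  int max_sweeps = 500, bool debug = false) {
  Penalty p = decode_penalty(pen);
  const arma::uword n = y.n_elem, pm = X.n_cols, pc = C.n_cols;
  const double dscale = (glm_family == 1) ? 0.25 : 1.0;

  arma::vec dX(pm), dC(pc);
  for (arma::uword j = 0; j < pm; ++j) dX[j] = dscale * arma::dot(X.col(j), X.col(j));
  for (arma::uword j = 0; j < pc; ++j) dC[j] = dscale * arma::dot(C.col(j), C.col(j));

  arma::vec eta = C * alpha + X * beta;
  arma::vec mu(n);
  auto refresh_mu = [&]() {
    if (glm_family == 1)
      for (arma::uword i = 0; i < n; ++i) mu[i] = logistic_mu(eta[i]);
    else
      mu = eta;
  };
  refresh_mu();

  std::vector<double> trace;
  auto record = [&]() {
    if (!debug) return;
    double obj = work_loglik(y, eta, glm_family);
    for (arma::uword j = 0; j < pm; ++j) {
      double w = p.w.n_elem ? p.w[j] : 1.0;
      obj -= penalty_value(std::fabs(beta[j]), p, w);
    }
    trace.push_back(obj);
  };
  record();

  // one pass over a coordinate set; returns max |delta|
  auto sweep = [&](const std::vector<arma::uword> &idx) {
    double maxd = 0.0;
    for (arma::uword j = 0; j < pc; ++j) {
      if (dC[j] <= 0.0) continue;
      double g = arma::dot(C.col(j), y - mu);
      double del = g / dC[j];
      if (del != 0.0) {
        alpha[j] += del;
        eta += del * C.col(j);
        refresh_mu();
        maxd = std::max(maxd, std::fabs(del));
      }
      record();
    }
    for (arma::uword k = 0; k < idx.size(); ++k) {
      const arma::uword j = idx[k];
      if (dX[j] <= 0.0) continue;
      double g = arma::dot(X.col(j), y - mu);
      double z = beta[j] + g / dX[j];
      double w = p.w.n_elem ? p.w[j] : 1.0;
      double bnew = cd_update(z, dX[j], p, w);
      if (p.family == NEG && bnew != beta[j]) {
        // safeguarded search is approximate: never accept a surrogate loss
        auto sf = [&](double b) {
          return -0.5 * dX[j] * (b - z) * (b - z) -
                 penalty_value(std::fabs(b), p, w);
        };
        if (sf(bnew) < sf(beta[j])) bnew = beta[j];
      }
      double del = bnew - beta[j];
      if (del != 0.0) {
        beta[j] = bnew;
        eta += del * X.col(j);
        refresh_mu();
        maxd = std::max(maxd, std::fabs(del));
      }
      record();
    }
    return maxd;
  };

  std::vector<arma::uword> full(order.begin(), order.end());
  bool converged = false;
  int sweeps = 0;
  if (debug) {
    // plain cyclic sweeps (objective recorded after every update)
    while (sweeps < max_sweeps) {
      double d_full = sweep(full);
      ++sweeps;
      if (d_full < tol) { converged = true; break; }
    }
  } else {
    // active-set cycling with a BLAS gradient screen for entry checks:
    // cycle the nonzero set to convergence, then compute all coordinate
    // gradients in one matrix-vector product and update (exactly, in the
    // given order) only coordinates whose surrogate update would move.
    while (sweeps < max_sweeps) {
      std::vector<arma::uword> act;
      for (arma::uword k = 0; k < full.size(); ++k)
        if (beta[full[k]] != 0.0) act.push_back(full[k]);
      while (sweeps < max_sweeps) {
        double d_act = sweep(act);
        ++sweeps;
        if (d_act < tol) break;
      }
      arma::vec gall = X.t() * (y - mu);
      std::vector<arma::uword> cand;
      for (arma::uword k = 0; k < full.size(); ++k) {
        const arma::uword j = full[k];
        if (dX[j] <= 0.0) continue;
        double z = beta[j] + gall[j] / dX[j];
        double w = p.w.n_elem ? p.w[j] : 1.0;
        if (std::fabs(cd_update(z, dX[j], p, w) - beta[j]) >= tol)
          cand.push_back(j);
      }
      if (cand.empty()) { converged = true; break; }
      double d_c = sweep(cand);
      ++sweeps;
      if (d_c < tol) { converged = true; break; }
    }
  }

  double ll = work_loglik(y, eta, glm_family);
  double rss = arma::dot(y - eta, y - eta);
  return List::create(_["beta"] = beta, _["alpha"] = alpha,
                      _["loglik_work"] = ll, _["rss"] = rss,
                      _["sweeps"] = sweeps, _["converged"] = converged,
                      _["objective_trace"] = trace);
}

// Per-marker logistic regression scan: for each column g_j of G fit
// y ~ C + g_j by IRLS and return the maximized log-likelihood and the
// marker coefficient. The covariate-only null fit is done on the R side.
// [[Rcpp::export]]
List cpp_scan_logistic(const arma::mat &G, const arma::mat &C,
                       const arma::vec &y, const arma::vec &start,
                       double tol = 1e-8, int maxit = 50) {
  const arma::uword n = y.n_elem, pm = G.n_cols, pc = C.n_cols;
  arma::vec loglik(pm), effect(pm);
  arma::ivec conv(pm, arma::fill::ones);

  arma::mat A(n, pc + 1);
  A.cols(0, pc - 1) = C;
  for (arma::uword j = 0; j < pm; ++j) {
    arma::vec g = G.col(j);
    if (arma::var(g) <= 0.0) {  // monomorphic: no added likelihood
      arma::vec eta0 = C * start;
      loglik[j] = work_loglik(y, eta0, 1);
      effect[j] = 0.0;
      conv[j] = 2;  // flag monomorphic
      continue;
    }
    A.col(pc) = g;
    arma::vec b(pc + 1, arma::fill::zeros);
    b.head(pc) = start;
    double ll_old = -arma::datum::inf, ll = 0.0;
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      arma::vec eta = A * b;
      arma::vec mu(n), wv(n);
      for (arma::uword i = 0; i < n; ++i) {
        mu[i] = logistic_mu(eta[i]);
        wv[i] = std::max(mu[i] * (1.0 - mu[i]), 1e-10);
      }
      arma::mat AtWA = A.t() * (A.each_col() % wv);
      arma::vec grad = A.t() * (y - mu);
      arma::vec step;
      if (!arma::solve(step, AtWA, grad, arma::solve_opts::likely_sympd)) break;
      // step-halving to keep the likelihood non-decreasing
      double t = 1.0;
      for (int h = 0; h < 20; ++h) {
        arma::vec bc = b + t * step;
        arma::vec ec = A * bc;
        ll = work_loglik(y, ec, 1);
        if (std::isfinite(ll) && ll >= ll_old - 1e-12) { b = bc; break; }
        t *= 0.5;
      }
      if (std::fabs(ll - ll_old) < tol * (std::fabs(ll) + 1.0)) { ok = true; break; }
      ll_old = ll;
    }
    loglik[j] = ll;
    effect[j] = b[pc];
    conv[j] = ok ? 1 : 0;
  }
  return List::create(_["loglik"] = loglik, _["effect"] = effect,
                      _["converged"] = conv);
}
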