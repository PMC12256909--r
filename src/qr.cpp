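// Core numerics for univariate quantile regression (intercept + slope) and
// the m-of-n bootstrap refitter.
//
// The check loss sum_i rho_tau(y_i - a - b g_i) is convex and piecewise
// linear in (a, b).  For fixed slope b the optimal intercept is an exact
// tau-th sample quantile of the residuals y - b g (order statistic
// r_(ceil(n*tau))), so the slope can be found by minimising the convex
// profiled objective f(b) = min_a L(a, b) with a bracketed golden-section
// search.  The contract downstream is objective optimality, not a
// particular vertex of the (possibly non-unique) solution set.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// minimiser of sum_i rho_tau(r_i - a) over a: the order statistic
// r_(ceil(n*tau)) (1-based).  Mutates r (partial sort).
static double tau_quantile_inplace(std::vector<double>& r, double tau) {
  const int n = static_cast<int>(r.size());
  int k = static_cast<int>(std::ceil(n * tau));
  if (k < 1) k = 1;
  if (k > n) k = n;
  std::nth_element(r.begin(), r.begin() + (k - 1), r.end());
  return r[k - 1];
}

// sum of rho_tau over (permuted) residuals r, shifted by intercept a
static double rho_sum(const std::vector<double>& r, double a, double tau) {
  double s = 0.0;
  for (size_t i = 0; i < r.size(); ++i) {
    const double d = r[i] - a;
    s += d * (d < 0.0 ? (tau - 1.0) : tau);
  }
  return s;
}

struct QrFit {
  double intercept;
  double slope;
  double objective;
  bool converged;
};

// profiled objective: residuals into work (mutated), optimal intercept out
static double profile_obj(const std::vector<double>& y,
                          const std::vector<double>& g, double b, double tau,
                          std::vector<double>& work, double* a_out) {
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) work[i] = y[i] - b * g[i];
  const double a = tau_quantile_inplace(work, tau);
  if (a_out) *a_out = a;
  return rho_sum(work, a, tau);
}

static QrFit qr_fit_core(const std::vector<double>& y,
                         const std::vector<double>& g, double tau,
                         std::vector<double>& work) {
  const size_t n = y.size();
  QrFit fit{0.0, 0.0, 0.0, true};

  double my = 0.0, mg = 0.0;
  for (size_t i = 0; i < n; ++i) {
    my += y[i];
    mg += g[i];
  }
  my /= n;
  mg /= n;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const double dg = g[i] - mg, dy = y[i] - my;
    sxy += dg * dy;
    sxx += dg * dg;
    syy += dy * dy;
  }

  if (sxx <= 1e-24 * (1.0 + syy)) {
    // degenerate predictor: intercept-only fit, slope pinned at 0
    fit.slope = 0.0;
    fit.objective = profile_obj(y, g, 0.0, tau, work, &fit.intercept);
    return fit;
  }

  const double b0 = sxy / sxx;
  const double scale = std::sqrt(syy / sxx);  // sd(y)/sd(g)
  double w = 2.0 * (scale + std::fabs(b0) + 1.0);

  // expand until the minimiser is bracketed (f convex and coercive in b)
  double lo = b0 - w, hi = b0 + w;
  const double f0 = profile_obj(y, g, b0, tau, work, nullptr);
  int guard = 0;
  while (profile_obj(y, g, lo, tau, work, nullptr) <= f0 && guard++ < 60)
    lo -= (w *= 1.8);
  w = 2.0 * (scale + std::fabs(b0) + 1.0);
  guard = 0;
  while (profile_obj(y, g, hi, tau, work, nullptr) <= f0 && guard++ < 60)
    hi += (w *= 1.8);

  const double gr = 0.6180339887498949;
  double x1 = hi - gr * (hi - lo);
  double x2 = lo + gr * (hi - lo);
  double f1 = profile_obj(y, g, x1, tau, work, nullptr);
  double f2 = profile_obj(y, g, x2, tau, work, nullptr);
  const double btol = 1e-12 * (1.0 + std::fabs(b0) + scale);
  int it = 0;
  for (; it < 220 && (hi - lo) > btol; ++it) {
    if (f1 <= f2) {
      hi = x2;
      x2 = x1;
      f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = profile_obj(y, g, x1, tau, work, nullptr);
    } else {
      lo = x1;
      x1 = x2;
      f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = profile_obj(y, g, x2, tau, work, nullptr);
    }
  }
  fit.converged = (hi - lo) <= 1e-6 * (1.0 + std::fabs(b0) + scale);
  double b = (f1 <= f2) ? x1 : x2;
  // the unconstrained LS slope is a candidate too (flat-kink degeneracies)
  if (f0 < std::min(f1, f2)) b = b0;
  fit.slope = b;
  fit.objective = profile_obj(y, g, b, tau, work, &fit.intercept);
  return fit;
}

// [[Rcpp::export]]
double cpp_check_loss(NumericVector r, double tau) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < r.size(); ++i) {
    const double d = r[i];
    s += d * (d < 0.0 ? (tau - 1.0) : tau);
  }
  return s;
}

// [[Rcpp::export]]
List cpp_qr_fit(NumericVector y, NumericVector g, double tau) {
  std::vector<double> yv(y.begin(), y.end()), gv(g.begin(), g.end());
  std::vector<double> work(yv.size());
  QrFit fit = qr_fit_core(yv, gv, tau, work);
  return List::create(Named("intercept") = fit.intercept,
                      Named("slope") = fit.slope,
                      Named("objective") = fit.objective,
                      Named("converged") = fit.converged);
}

// [[Rcpp::export]]
NumericMatrix cpp_qr_grid(NumericVector y, NumericVector g, NumericVector taus) {
  std::vector<double> yv(y.begin(), y.end()), gv(g.begin(), g.end());
  std::vector<double> work(yv.size());
  const int K = taus.size();
  NumericMatrix out(K, 4);
  for (int k = 0; k < K; ++k) {
    QrFit fit = qr_fit_core(yv, gv, taus[k], work);
    out(k, 0) = fit.intercept;
    out(k, 1) = fit.slope;
    out(k, 2) = fit.objective;
    out(k, 3) = fit.converged ? 1.0 : 0.0;
  }
  return out;
}

// Joint refit of the OLS slope and all quantile slopes on each bootstrap
// resample.  idx is an m x B matrix of 1-based row indices; the same
// resample feeds the OLS and every tau so the (K+1)-dimensional covariance
// is coherent.  Returns a B x (K+1) matrix: column 1 the OLS slope,
// columns 2..K+1 the quantile slopes.
// [[Rcpp::export]]
NumericMatrix cpp_boot_fit(NumericVector y, NumericVector g, NumericVector taus,
                           IntegerMatrix idx) {
  const int m = idx.nrow();
  const int B = idx.ncol();
  const int K = taus.size();
  NumericMatrix out(B, K + 1);
  std::vector<double> yb(m), gb(m), work(m);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < m; ++i) {
      const int j = idx(i, b) - 1;
      yb[i] = y[j];
      gb[i] = g[j];
    }
    double my = 0.0, mg = 0.0;
    for (int i = 0; i < m; ++i) {
      my += yb[i];
      mg += gb[i];
    }
    my /= m;
    mg /= m;
    double sxy = 0.0, sxx = 0.0;
    for (int i = 0; i < m; ++i) {
      sxy += (gb[i] - mg) * (yb[i] - my);
      sxx += (gb[i] - mg) * (gb[i] - mg);
    }
    out(b, 0) = sxx > 0.0 ? sxy / sxx : NA_REAL;
    for (int k = 0; k < K; ++k) {
      QrFit fit = qr_fit_core(yb, gb, taus[k], work);
      out(b, k + 1) = fit.slope;
    }
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
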