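#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cfloat>
#include <cstdio>
using namespace Rcpp;

// Penalized mixture-weight estimation with a fixed component likelihood
// matrix: L is n x K with L(i,k) = density of observation i under component
// k; component 0 is the point mass at zero. A Dirichlet-style penalty
// (penalty - 1) * log(w0) favors the null component, matching the
// adaptive-shrinkage convention. Observations may carry nonnegative weights
// (used for bootstrap refits without rebuilding L).
//
// Plain EM mixes very slowly when components are nearly indistinguishable
// (tiny sds against large se), which is exactly where the null weight
// matters; the fixed-point iteration is therefore SQUAREM-accelerated with
// a monotonicity safeguard: an extrapolated step is only accepted when it
// does not decrease the penalized log-likelihood, otherwise the plain
// double EM step is kept. The recorded trace is nondecreasing.

static double penalized_ll(const NumericMatrix& L, const NumericVector& w_obs,
                           const std::vector<double>& pi, double pen0) {
  const int n = L.nrow(), K = L.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w_obs[i] <= 0) continue;
    double mix = 0.0;
    for (int k = 0; k < K; ++k) mix += pi[k] * L(i, k);
    if (mix <= 0) mix = DBL_MIN;
    ll += w_obs[i] * std::log(mix);
  }
  if (pen0 > 0) ll += pen0 * std::log(std::max(pi[0], DBL_MIN));
  return ll;
}

static void em_step(const NumericMatrix& L, const NumericVector& w_obs,
                    const std::vector<double>& pi, double pen0, double denom,
                    std::vector<double>& out) {
  const int n = L.nrow(), K = L.ncol();
  std::fill(out.begin(), out.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    const double wi = w_obs[i];
    if (wi <= 0) continue;
    double mix = 0.0;
    for (int k = 0; k < K; ++k) mix += pi[k] * L(i, k);
    if (mix <= 0) mix = DBL_MIN;
    for (int k = 0; k < K; ++k) out[k] += wi * pi[k] * L(i, k) / mix;
  }
  out[0] += pen0;
  double s = 0.0;
  for (int k = 0; k < K; ++k) { out[k] /= denom; if (out[k] < 0) out[k] = 0; s += out[k]; }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// Exact coordinate ascent between the point mass (component 0) and each
// other component: along the segment w0 + wk = s the penalized
// log-likelihood is strictly concave in w0, so the maximizer is found by
// bisection on the derivative. This removes the null-weight leakage into
// statistically indistinguishable small-sd components, where EM's rate of
// convergence collapses. Returns the updated penalized log-likelihood.
static double coord_polish(const NumericMatrix& L, const NumericVector& w_obs,
                           std::vector<double>& pi, double pen0) {
  const int n = L.nrow(), K = L.ncol();
  std::vector<double> mix(n);
  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int k = 0; k < K; ++k) m += pi[k] * L(i, k);
    mix[i] = (m <= 0) ? DBL_MIN : m;
  }
  for (int k = 1; k < K; ++k) {
    const double s = pi[0] + pi[k];
    if (s <= 1e-14) continue;
    // derivative of f(t) = sum_i w_i log(base_i + t L0 + (s-t) Lk) + pen0 log t
    auto deriv = [&](double t) {
      double d = (pen0 > 0) ? pen0 / std::max(t, 1e-300) : 0.0;
      for (int i = 0; i < n; ++i) {
        if (w_obs[i] <= 0) continue;
        double base = mix[i] - pi[0] * L(i, 0) - pi[k] * L(i, k);
        double m = base + t * L(i, 0) + (s - t) * L(i, k);
        if (m <= 0) m = DBL_MIN;
        d += w_obs[i] * (L(i, 0) - L(i, k)) / m;
      }
      return d;
    };
    double lo = (pen0 > 0) ? s * 1e-12 : 0.0, hi = s, t;
    if (deriv(hi) >= 0) t = hi;
    else if (deriv(lo) <= 0) t = lo;
    else {
      for (int it = 0; it < 30; ++it) {
        t = 0.5 * (lo + hi);
        if (deriv(t) > 0) lo = t; else hi = t;
      }
      t = 0.5 * (lo + hi);
    }
    if (t != pi[0]) {
      for (int i = 0; i < n; ++i) {
        mix[i] += (t - pi[0]) * L(i, 0) + (s - t - pi[k]) * L(i, k);
        if (mix[i] <= 0) mix[i] = DBL_MIN;
      }
      pi[0] = t; pi[k] = s - t;
    }
  }
  return penalized_ll(L, w_obs, pi, pen0);
}

static void project_simplex(std::vector<double>& x) {
  double s = 0.0;
  for (double& v : x) { if (v < 1e-15) v = 1e-15; s += v; }
  for (double& v : x) v /= s;
}

// [[Rcpp::export]]
List em_mix_weights(const NumericMatrix& L, const NumericVector& w_obs,
                    double penalty, double tol, int maxiter,
                    bool keep_trace, bool polish = true,
                    Nullable<NumericVector> init = R_NilValue) {
  const int K = L.ncol();
  std::vector<double> pi(K);
  if (init.isNotNull()) {
    NumericVector w0(init);
    double s = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = std::max(w0[k], 1e-8); s += pi[k]; }
    for (int k = 0; k < K; ++k) pi[k] /= s;
  } else {
    for (int k = 0; k < K; ++k) pi[k] = (k == 0) ? 0.5 : 0.5 / (K - 1);
  }
  if (K == 1) pi[0] = 1.0;

  double wsum = 0.0;
  for (R_xlen_t i = 0; i < w_obs.size(); ++i) wsum += w_obs[i];
  const double pen0 = penalty - 1.0;
  const double denom = wsum + pen0;

  std::vector<double> t1(K), t2(K), cand(K);
  std::vector<double> trace;
  double ll = penalized_ll(L, w_obs, pi, pen0);
  if (keep_trace) trace.push_back(ll);
  bool converged = false;
  int it = 0, n_evals = 0;

  while (it < maxiter) {
    // SQUAREM cycle: two EM steps plus safeguarded extrapolation
    em_step(L, w_obs, pi, pen0, denom, t1);
    em_step(L, w_obs, t1, pen0, denom, t2);
    it += 2;
    double sr2 = 0.0, sv2 = 0.0;
    for (int k = 0; k < K; ++k) {
      double r = t1[k] - pi[k];
      double v = (t2[k] - t1[k]) - r;
      sr2 += r * r; sv2 += v * v;
    }
    double ll_new;
    if (sv2 > 0) {
      double alpha = -std::sqrt(sr2 / sv2);
      if (alpha > -1.0) alpha = -1.0;
      for (int k = 0; k < K; ++k) {
        double r = t1[k] - pi[k];
        double v = (t2[k] - t1[k]) - r;
        cand[k] = pi[k] - 2.0 * alpha * r + alpha * alpha * v;
      }
      project_simplex(cand);
      // one stabilizing EM step after extrapolation (standard SQUAREM)
      em_step(L, w_obs, cand, pen0, denom, t1);
      ++it;
      double ll_cand = penalized_ll(L, w_obs, t1, pen0);
      ++n_evals;
      if (R_finite(ll_cand) && ll_cand >= ll - 1e-12) {
        pi = t1; ll_new = ll_cand;
      } else {
        pi = t2; ll_new = penalized_ll(L, w_obs, pi, pen0); ++n_evals;
      }
    } else {
      pi = t2; ll_new = penalized_ll(L, w_obs, pi, pen0); ++n_evals;
    }
    if (ll_new < ll) ll_new = ll;   // safeguard: trace is nondecreasing
    if (keep_trace) trace.push_back(ll_new);
    if (std::fabs(ll_new - ll) < tol) { ll = ll_new; converged = true; break; }
    ll = ll_new;
  }

  // alternate exact null-coordinate polish with short EM bursts until the
  // penalized log-likelihood is stationary
  for (int round = 0; polish && round < 5; ++round) {
    double ll_pol = coord_polish(L, w_obs, pi, pen0);
    if (ll_pol < ll) ll_pol = ll;      // numerical guard; ascent by design
    if (keep_trace) trace.push_back(ll_pol);
    bool done = std::fabs(ll_pol - ll) < tol;
    ll = ll_pol;
    if (done) { converged = true; break; }
    em_step(L, w_obs, pi, pen0, denom, t1);
    pi = t1;
    ++it;
    double ll_em = penalized_ll(L, w_obs, pi, pen0);
    if (ll_em < ll) ll_em = ll;
    if (keep_trace) trace.push_back(ll_em);
    ll = ll_em;
  }

  return List::create(_["weights"] = NumericVector(pi.begin(), pi.end()),
                      _["loglik"] = ll,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = it,
                      _["converged"] = converged);
}

// Posterior responsibilities under fitted weights (n x K).
// [[Rcpp::export]]
NumericMatrix mix_responsibilities(const NumericMatrix& L,
                                   const NumericVector& weights) {
  const int n = L.nrow(), K = L.ncol();
  NumericMatrix R(n, K);
  for (int i = 0; i < n; ++i) {
    double mix = 0.0;
    for (int k = 0; k < K; ++k) mix += weights[k] * L(i, k);
    if (mix <= 0) mix = DBL_MIN;
    for (int k = 0; k < K; ++k) R(i, k) = weights[k] * L(i, k) / mix;
  }
  return R;
}

// FNV-1a 64-bit over raw bytes; used for cache-file content keys.
// [[Rcpp::export]]
std::string fnv1a64(const RawVector& bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
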