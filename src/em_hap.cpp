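#include <Rcpp.h>
using namespace Rcpp;

// EM for a mixture over founder haplotypes, accelerated with SQUAREM.
//
// expL: reads x founders matrix of exp(loglik - per-read max loglik);
//       the subtracted row maxima cancel in the posteriors and add a
//       frequency-independent constant to the data log-likelihood.
//
// The plain EM map is
//   F(f)_h = (1/R) sum_r f_h expL(r,h) / sum_h' f_h' expL(r,h'),
// whose fixed points are the stationary points of the data log-likelihood
//   ll(f) = sum_r log sum_h f_h expL(r,h),
// which is concave in f on the simplex, so the maximiser is unique (up to
// flat directions) and independent of the interior starting point.
//
// SQUAREM (Varadhan & Roland 2008) extrapolates two consecutive EM steps:
//   r = F(f)-f, v = F(F(f))-2F(f)+f, alpha = -|r|/|v|,
//   f* = f - 2 alpha r + alpha^2 v,
// backtracking alpha toward -1 (which reduces to plain EM) while f* leaves
// the simplex, and stabilising with one EM step. A monotonicity safeguard
// rejects any extrapolation that would decrease ll, so the reported
// log-likelihood trace is non-decreasing exactly as for plain EM.
//
// Convergence: max |F(f) - f| < tol (change under one EM map application).
// n_iter counts EM map applications. The trace records ll at the accepted
// iterates (up to the additive row-max constant).

// one EM map application: fills fnew, returns ll at f
static double em_step(const NumericMatrix& expL, const std::vector<double>& f,
                      std::vector<double>& fnew, std::vector<double>& denom) {
  const int R = expL.nrow(), H = expL.ncol();
  std::fill(denom.begin(), denom.end(), 0.0);
  for (int h = 0; h < H; ++h) {
    const double fh = f[h];
    if (fh == 0.0) continue;
    const double* col = &expL(0, h);
    for (int r = 0; r < R; ++r) denom[r] += fh * col[r];
  }
  double ll = 0.0;
  for (int r = 0; r < R; ++r) ll += std::log(denom[r]);
  for (int h = 0; h < H; ++h) {
    const double fh = f[h];
    double acc = 0.0;
    if (fh > 0.0) {
      const double* col = &expL(0, h);
      for (int r = 0; r < R; ++r) acc += col[r] / denom[r];
      acc *= fh / R;
    }
    fnew[h] = acc;
  }
  return ll;
}

static double ll_only(const NumericMatrix& expL, const std::vector<double>& f) {
  const int R = expL.nrow(), H = expL.ncol();
  std::vector<double> denom(R, 0.0);
  for (int h = 0; h < H; ++h) {
    const double fh = f[h];
    if (fh == 0.0) continue;
    const double* col = &expL(0, h);
    for (int r = 0; r < R; ++r) denom[r] += fh * col[r];
  }
  double ll = 0.0;
  for (int r = 0; r < R; ++r) ll += std::log(denom[r]);
  return ll;
}

static double max_abs_diff(const std::vector<double>& a,
                           const std::vector<double>& b) {
  double m = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    double d = std::fabs(a[i] - b[i]);
    if (d > m) m = d;
  }
  return m;
}

// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericMatrix expL, NumericVector f0, double tol, int max_iter) {
  const int R = expL.nrow(), H = expL.ncol();
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> f1(H), f2(H), fp(H), fs(H), denom(R);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    // two EM steps
    double ll0 = em_step(expL, f, f1, denom); ++it;
    ll_trace.push_back(ll0);
    if (max_abs_diff(f1, f) < tol) { f = f1; converged = true; break; }
    if (it >= max_iter) { f = f1; break; }
    double ll1 = em_step(expL, f1, f2, denom); ++it;
    ll_trace.push_back(ll1);
    if (max_abs_diff(f2, f1) < tol) { f = f2; converged = true; break; }
    if (it >= max_iter) { f = f2; break; }
    // extrapolate
    double rr = 0.0, vv = 0.0;
    for (int h = 0; h < H; ++h) {
      double rh = f1[h] - f[h];
      double vh = f2[h] - 2.0 * f1[h] + f[h];
      rr += rh * rh;
      vv += vh * vh;
    }
    if (vv == 0.0) { f = f2; converged = true; break; }
    double alpha = -std::sqrt(rr / vv);
    if (alpha > -1.0) alpha = -1.0;
    // backtrack toward plain EM (alpha = -1) while leaving the simplex
    for (int bt = 0; bt < 10; ++bt) {
      bool ok = true;
      double s = 0.0;
      for (int h = 0; h < H; ++h) {
        double x = f[h] - 2.0 * alpha * (f1[h] - f[h]) +
                   alpha * alpha * (f2[h] - 2.0 * f1[h] + f[h]);
        if (x < 0.0) { ok = false; break; }
        fp[h] = x;
        s += x;
      }
      if (ok && s > 0.0) {
        for (int h = 0; h < H; ++h) fp[h] /= s;
        break;
      }
      alpha = (alpha - 1.0) / 2.0;
      if (bt == 9) fp = f2;  // give up extrapolating this round
    }
    // monotonicity safeguard: accept the extrapolated point only when it
    // does not decrease the log-likelihood reached by the two plain steps
    double ll2 = ll_only(expL, f2);
    double llp = ll_only(expL, fp);
    if (llp >= ll2) {
      // stabilise with one EM step from the extrapolated point
      em_step(expL, fp, fs, denom); ++it;
      if (max_abs_diff(fs, fp) < tol) {
        f = fs; converged = true;
        ll_trace.push_back(llp);
        break;
      }
      f = fs;
    } else {
      f = f2;
    }
  }
  // final log-likelihood at the returned iterate
  ll_trace.push_back(ll_only(expL, f));
  return List::create(
    _["freqs"] = NumericVector(f.begin(), f.end()),
    _["n_iter"] = it,
    _["converged"] = converged,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
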