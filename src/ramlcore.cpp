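#include <Rcpp.h>
using namespace Rcpp;

// Log of the per-variant likelihood ratio L1/L0 for the admixture mixture:
// L1 = N(z; eta, 1 + sigma^2), L0 = N(z; 0, 1), evaluated in log space so
// that large |z| cannot overflow.
static inline double log_ratio(double z, double eta, double s) {
  double v = 1.0 + s;
  double d = z - eta;
  return -0.5 * std::log(v) - 0.5 * (d * d / v - z * z);
}

// log((1 - alpha) + alpha * exp(t)), stable for t of either sign.
static inline double log_mix_term(double t, double alpha) {
  if (t > 0.0) {
    return t + std::log(alpha + (1.0 - alpha) * std::exp(-t));
  }
  return std::log1p(alpha * std::expm1(t));
}

// [[Rcpp::export]]
double cpp_mixture_loglik(NumericVector z, double alpha, double eta,
                          double sigma2) {
  const int m = z.size();
  double ll = 0.0;
  for (int i = 0; i < m; ++i) {
    ll += log_mix_term(log_ratio(z[i], eta, sigma2), alpha);
  }
  return ll;
}

// Derivative of the mixture log-likelihood in alpha, for fixed (eta, sigma2).
// With w_i = e^{t_i} - 1 each term is w_i / (1 + alpha w_i); the first
// derivative is monotone decreasing in alpha (the log-likelihood is concave
// in alpha), so the inner maximisation is a safeguarded 1-D Newton search.
// t is capped so that w^2 stays finite.
static inline double cap_w(double t) {
  return std::expm1(t > 350.0 ? 350.0 : t);
}

static void d12_dalpha(const std::vector<double>& t, double alpha,
                       double* d1, double* d2) {
  double s1 = 0.0, s2 = 0.0;
  for (size_t i = 0; i < t.size(); ++i) {
    double w = cap_w(t[i]);
    double denom = 1.0 + alpha * w;
    double r = w / denom;
    s1 += r;
    s2 -= r * r;
  }
  *d1 = s1;
  *d2 = s2;
}

static double profile_alpha(const std::vector<double>& t, double amin,
                            double amax) {
  double d1, d2;
  d12_dalpha(t, amax, &d1, &d2);
  if (d1 >= 0.0) return amax;
  d12_dalpha(t, amin, &d1, &d2);
  if (d1 <= 0.0) return amin;
  double lo = amin, hi = amax, a = 0.5 * (amin + amax);
  for (int it = 0; it < 40; ++it) {
    d12_dalpha(t, a, &d1, &d2);
    if (d1 > 0.0) lo = a; else hi = a;
    if (hi - lo < 1e-10 * (amax - amin)) break;
    double step = (d2 < 0.0) ? a - d1 / d2 : R_NaReal;
    if (!R_FINITE(step) || step <= lo || step >= hi) step = 0.5 * (lo + hi);
    if (std::abs(d1) < 1e-12) break;
    a = step;
  }
  return a;
}

static double profile_ll_t(const std::vector<double>& t, double amin,
                           double amax, double* alpha_out) {
  double a = profile_alpha(t, amin, amax);
  double ll = 0.0;
  for (size_t i = 0; i < t.size(); ++i) ll += log_mix_term(t[i], a);
  if (alpha_out) *alpha_out = a;
  return ll;
}

// Profile log-likelihood over alpha at fixed (eta, sigma2).
// [[Rcpp::export]]
List cpp_profile_ll(NumericVector z, double eta, double sigma2, double amin,
                    double amax) {
  const int m = z.size();
  std::vector<double> t(m);
  for (int i = 0; i < m; ++i) t[i] = log_ratio(z[i], eta, sigma2);
  double a;
  double ll = profile_ll_t(t, amin, amax, &a);
  return List::create(_["loglik"] = ll, _["alpha"] = a);
}

// Coarse scan of the profile log-likelihood over an (eta, sigma2) grid,
// used to seed the bounded optimiser with the best basins.
// [[Rcpp::export]]
NumericMatrix cpp_profile_grid(NumericVector z, NumericVector etas,
                               NumericVector ss, double amin, double amax) {
  const int m = z.size(), ne = etas.size(), ns = ss.size();
  NumericMatrix out(ne, ns);
  std::vector<double> t(m);
  for (int j = 0; j < ns; ++j) {
    for (int i = 0; i < ne; ++i) {
      for (int k = 0; k < m; ++k) t[k] = log_ratio(z[k], etas[i], ss[j]);
      out(i, j) = profile_ll_t(t, amin, amax, nullptr);
    }
  }
  return out;
}

// ---- internal bounded Nelder-Mead on (eta, sigma2) with alpha profiled ----
// Used for the high-volume permutation path; the user-facing fit refines with
// BOBYQA from R. Coordinates are clamped to the box.

struct ProfObj {
  const NumericVector& z;
  double el, eu, sl, su, amin, amax;
  std::vector<double> w;
  ProfObj(const NumericVector& z_, double el_, double eu_, double sl_,
          double su_, double amin_, double amax_)
      : z(z_), el(el_), eu(eu_), sl(sl_), su(su_), amin(amin_), amax(amax_),
        w(z_.size()) {}
  // profile negative log-likelihood with w = e^t - 1 computed once; t is
  // capped far beyond any realistic score statistic, keeping w^2 finite
  double negll(double eta, double s) {
    eta = std::min(std::max(eta, el), eu);
    s = std::min(std::max(s, sl), su);
    const int m = z.size();
    for (int k = 0; k < m; ++k) w[k] = cap_w(log_ratio(z[k], eta, s));
    // safeguarded Newton for the inner alpha maximum
    double d1 = 0.0, d2 = 0.0;
    auto deriv = [&](double a) {
      d1 = 0.0; d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double r = w[k] / (1.0 + a * w[k]);
        d1 += r; d2 -= r * r;
      }
    };
    double a;
    deriv(amax);
    if (d1 >= 0.0) {
      a = amax;
    } else {
      deriv(amin);
      if (d1 <= 0.0) {
        a = amin;
      } else {
        double lo = amin, hi = amax;
        a = 0.5 * (amin + amax);
        for (int it = 0; it < 30; ++it) {
          deriv(a);
          if (d1 > 0.0) lo = a; else hi = a;
          if (hi - lo < 1e-9 || std::abs(d1) < 1e-12) break;
          double step = (d2 < 0.0) ? a - d1 / d2 : 0.5 * (lo + hi);
          if (!R_FINITE(step) || step <= lo || step >= hi)
            step = 0.5 * (lo + hi);
          a = step;
        }
      }
    }
    double ll = 0.0;
    for (int k = 0; k < m; ++k) ll += std::log1p(a * w[k]);
    return -ll;
  }
};

static void nelder_mead2(ProfObj& f, double x0, double y0, double step_x,
                         double step_y, int maxit, double tol, double* xb,
                         double* yb, double* fb) {
  double px[3] = {x0, x0 + step_x, x0};
  double py[3] = {y0, y0, y0 + step_y};
  double pf[3];
  for (int i = 0; i < 3; ++i) pf[i] = f.negll(px[i], py[i]);
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (pf[i] < pf[lo]) lo = i;
      if (pf[i] > pf[hi]) hi = i;
    }
    if (pf[hi] - pf[lo] < tol) break;
    int mid = 3 - lo - hi;
    if (mid == lo || mid == hi) mid = (lo + 1) % 3;  // degenerate guard
    double cx = 0.5 * (px[lo] + px[mid]), cy = 0.5 * (py[lo] + py[mid]);
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double fr = f.negll(rx, ry);
    if (fr < pf[lo]) {
      double ex = cx + 2.0 * (cx - px[hi]), ey = cy + 2.0 * (cy - py[hi]);
      double fe = f.negll(ex, ey);
      if (fe < fr) { px[hi] = ex; py[hi] = ey; pf[hi] = fe; }
      else { px[hi] = rx; py[hi] = ry; pf[hi] = fr; }
    } else if (fr < pf[mid]) {
      px[hi] = rx; py[hi] = ry; pf[hi] = fr;
    } else {
      double kx = cx + 0.5 * (px[hi] - cx), ky = cy + 0.5 * (py[hi] - cy);
      double fk = f.negll(kx, ky);
      if (fk < pf[hi]) { px[hi] = kx; py[hi] = ky; pf[hi] = fk; }
      else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          pf[i] = f.negll(px[i], py[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (pf[i] < pf[lo]) lo = i;
  *xb = px[lo]; *yb = py[lo]; *fb = pf[lo];
}

static double fit_one(const NumericVector& z, const NumericVector& etas,
                      const NumericVector& ss, double el, double eu, double sl,
                      double su, double amin, double amax) {
  ProfObj f(z, el, eu, sl, su, amin, amax);
  // coarse scan; keep the best three starts separated in eta to cover
  // distinct basins (the profile likelihood can be multimodal in eta)
  const int n_top = 3;
  double te[n_top], ts[n_top], tv[n_top];
  for (int k = 0; k < n_top; ++k) tv[k] = R_PosInf;
  for (int j = 0; j < ss.size(); ++j) {
    for (int i = 0; i < etas.size(); ++i) {
      double v = f.negll(etas[i], ss[j]);
      for (int k = 0; k < n_top; ++k) {
        if (v < tv[k]) {
          bool same_basin = false;
          for (int q = 0; q < k; ++q)
            if (std::abs(etas[i] - te[q]) < 1.0) { same_basin = true; break; }
          if (same_basin) break;
          for (int q = n_top - 1; q > k; --q) {
            te[q] = te[q - 1]; ts[q] = ts[q - 1]; tv[q] = tv[q - 1];
          }
          te[k] = etas[i]; ts[k] = ss[j]; tv[k] = v;
          break;
        }
      }
    }
  }
  double best = R_PosInf;
  for (int k = 0; k < n_top; ++k) {
    if (!R_FINITE(tv[k])) continue;
    double xb, yb, fb;
    nelder_mead2(f, te[k], ts[k], 0.25, 0.5, 150, 1e-9, &xb, &yb, &fb);
    if (fb < best) best = fb;
  }
  double ll = -best;
  return ll > 0.0 ? ll : 0.0;
}

// Maximised admixture log-likelihood for each column of a z-statistic matrix
// (one column per permutation). Returns the clamped statistic Lambda >= 0.
// [[Rcpp::export]]
NumericVector cpp_lambda_many(NumericMatrix Z, NumericVector etas,
                              NumericVector ss, double el, double eu,
                              double sl, double su, double amin, double amax) {
  const int B = Z.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    NumericVector z = Z(_, b);
    out[b] = fit_one(z, etas, ss, el, eu, sl, su, amin, amax);
  }
  return out;
}
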