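// Inner computational kernel: two-compartment bolus concentrations and
// damped Gauss-Newton minimisation of the penalized MAP objective for the
// empirical Bayes random-effect estimates.  Kept in C++ because design
// evaluation solves this problem once per simulated replicate (thousands
// of times per candidate design).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Ctx {
  std::vector<double> times;   // observation times (min)
  double dose;                 // mg/kg
  double cl_typ, v1t, v2t, q;  // covariate-typical parameters
  double b;                    // proportional residual coefficient
  std::vector<double> winv;    // 1/omega^2 for the active effects
  std::vector<int> idx;        // active effect -> position in (cl, v1, v2)
};

// closed-form bi-exponential solution with repeated-root limit
double conc_one(double cl, double v1, double v2, double q, double dose,
                double t) {
  const double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  const double s = k10 + k12 + k21, p = k10 * k21;
  double d2 = s * s - 4.0 * p;
  if (d2 < 0.0) d2 = 0.0;
  const double disc = std::sqrt(d2);
  if (disc <= s * 1e-12) {
    const double lam = s / 2.0;
    return dose / v1 * std::exp(-lam * t) * (1.0 + (k21 - lam) * t);
  }
  const double a = (s + disc) / 2.0, be = (s - disc) / 2.0;
  const double ca = (a - k21) / disc, cb = (k21 - be) / disc;
  return dose / v1 * (ca * std::exp(-a * t) + cb * std::exp(-be * t));
}

void conc_eta(const Ctx& c, const std::vector<double>& eta,
              std::vector<double>& f) {
  double full[3] = {0.0, 0.0, 0.0};
  for (size_t k = 0; k < c.idx.size(); ++k) full[c.idx[k]] = eta[k];
  const double cl = c.cl_typ * std::exp(full[0]);
  const double v1 = c.v1t * std::exp(full[1]);
  const double v2 = c.v2t * std::exp(full[2]);
  for (size_t j = 0; j < c.times.size(); ++j)
    f[j] = conc_one(cl, v1, v2, c.q, c.dose, c.times[j]);
}

// penalized MAP objective; +Inf when the prediction degenerates
double map_obj(const Ctx& c, const std::vector<double>& y,
               const std::vector<double>& eta, std::vector<double>& f) {
  conc_eta(c, eta, f);
  double val = 0.0;
  for (size_t j = 0; j < f.size(); ++j) {
    if (!std::isfinite(f[j]) || f[j] <= 0.0)
      return std::numeric_limits<double>::infinity();
    const double g2 = c.b * c.b * f[j] * f[j];
    const double r = y[j] - f[j];
    val += r * r / g2 + std::log(g2);
  }
  for (size_t k = 0; k < eta.size(); ++k)
    val += eta[k] * eta[k] * c.winv[k];
  return val;
}

// solve the p x p system (H + lambda I) d = -g in place; returns false on
// a singular pivot
bool solve_damped(std::vector<double> H, std::vector<double> g,
                  double lambda, int p, std::vector<double>& d) {
  for (int i = 0; i < p; ++i) H[i * p + i] += lambda;
  // Gaussian elimination with partial pivoting
  std::vector<int> piv(p);
  for (int i = 0; i < p; ++i) piv[i] = i;
  for (int col = 0; col < p; ++col) {
    int best = col;
    double bv = std::fabs(H[piv[col] * p + col]);
    for (int r = col + 1; r < p; ++r) {
      const double v = std::fabs(H[piv[r] * p + col]);
      if (v > bv) { bv = v; best = r; }
    }
    if (bv < 1e-300) return false;
    std::swap(piv[col], piv[best]);
    const double pv = H[piv[col] * p + col];
    for (int r = col + 1; r < p; ++r) {
      const double m = H[piv[r] * p + col] / pv;
      if (m == 0.0) continue;
      for (int cc = col; cc < p; ++cc) H[piv[r] * p + cc] -= m * H[piv[col] * p + cc];
      g[piv[r]] -= m * g[piv[col]];
    }
  }
  d.assign(p, 0.0);
  for (int row = p - 1; row >= 0; --row) {
    double v = g[piv[row]];
    for (int cc = row + 1; cc < p; ++cc) v -= H[piv[row] * p + cc] * d[cc];
    d[row] = v / H[piv[row] * p + row];
  }
  for (int i = 0; i < p; ++i) d[i] = -d[i];
  return true;
}

struct GnResult {
  std::vector<double> eta;
  double obj;
  bool converged;
  int iters;
};

// damped Gauss-Newton with exact handling of the log-variance term in the
// gradient; only strictly decreasing steps are accepted
GnResult gn(const Ctx& c, const std::vector<double>& y,
            const std::vector<double>& start, int max_iter, double grad_tol,
            double step_tol) {
  const int p = (int)c.idx.size();
  const size_t m = c.times.size();
  GnResult res;
  res.eta = start;
  res.converged = false;
  res.iters = 0;
  std::vector<double> f(m), fp(m), fm(m);
  res.obj = map_obj(c, y, res.eta, f);
  if (!std::isfinite(res.obj)) return res;
  double lambda = 1e-3;
  const double h = 1e-6;
  std::vector<double> Jf(m * p), Jr(m * p), grad(p), H(p * p), d(p),
      cand(p), fc(m);
  for (int it = 1; it <= max_iter; ++it) {
    res.iters = it;
    conc_eta(c, res.eta, f);
    for (int k = 0; k < p; ++k) {
      std::vector<double> ep = res.eta, em = res.eta;
      ep[k] += h; em[k] -= h;
      conc_eta(c, ep, fp);
      conc_eta(c, em, fm);
      for (size_t j = 0; j < m; ++j) Jf[j * p + k] = (fp[j] - fm[j]) / (2 * h);
    }
    // residuals r = (y - f)/(b f); dr/deta = -(y/(b f^2)) df/deta
    double gmax = 0.0;
    for (int k = 0; k < p; ++k) grad[k] = 2.0 * res.eta[k] * c.winv[k];
    for (size_t j = 0; j < m; ++j) {
      const double r = (y[j] - f[j]) / (c.b * f[j]);
      const double w = -y[j] / (c.b * f[j] * f[j]);
      for (int k = 0; k < p; ++k) {
        Jr[j * p + k] = w * Jf[j * p + k];
        grad[k] += 2.0 * Jr[j * p + k] * r + 2.0 * Jf[j * p + k] / f[j];
      }
    }
    for (int k = 0; k < p; ++k)
      if (std::fabs(grad[k]) > gmax) gmax = std::fabs(grad[k]);
    if (gmax < grad_tol) { res.converged = true; break; }
    for (int a = 0; a < p; ++a)
      for (int bcol = 0; bcol < p; ++bcol) {
        double v = (a == bcol) ? 2.0 * c.winv[a] : 0.0;
        for (size_t j = 0; j < m; ++j) v += 2.0 * Jr[j * p + a] * Jr[j * p + bcol];
        H[a * p + bcol] = v;
      }
    bool improved = false;
    for (int tries = 0; tries < 25; ++tries) {
      if (solve_damped(H, grad, lambda, p, d)) {
        double stepnorm = 0.0;
        for (int k = 0; k < p; ++k) {
          cand[k] = res.eta[k] + d[k];
          stepnorm += d[k] * d[k];
        }
        stepnorm = std::sqrt(stepnorm);
        const double on = map_obj(c, y, cand, fc);
        if (std::isfinite(on) && on < res.obj) {
          res.eta = cand;
          res.obj = on;
          if (stepnorm < step_tol) res.converged = true;
          else lambda = std::max(lambda / 3.0, 1e-12);
          improved = true;
          break;
        }
      }
      lambda *= 4.0;
    }
    if (res.converged) break;
    if (!improved) { res.converged = gmax < 1e-4; break; }
  }
  return res;
}

// origin plus the 2^p corners of [-0.5, 0.5]^p
std::vector<std::vector<double> > start_points(int p) {
  std::vector<std::vector<double> > s;
  s.push_back(std::vector<double>(p, 0.0));
  const int n = 1 << p;
  for (int mask = 0; mask < n; ++mask) {
    std::vector<double> e(p);
    for (int k = 0; k < p; ++k) e[k] = (mask >> k & 1) ? 0.5 : -0.5;
    s.push_back(e);
  }
  return s;
}

GnResult solve_full(const Ctx& c, const std::vector<double>& y, int max_iter,
                    double grad_tol, double step_tol, const double* warm) {
  std::vector<std::vector<double> > starts = start_points((int)c.idx.size());
  if (warm) starts.insert(starts.begin(),
                          std::vector<double>(warm, warm + c.idx.size()));
  std::vector<double> f(c.times.size());
  size_t best = 0;
  double bv = std::numeric_limits<double>::infinity();
  std::vector<double> vals(starts.size());
  for (size_t i = 0; i < starts.size(); ++i) {
    vals[i] = map_obj(c, y, starts[i], f);
    if (vals[i] < bv) { bv = vals[i]; best = i; }
  }
  GnResult res = gn(c, y, starts[best], max_iter, grad_tol, step_tol);
  if (!res.converged) {
    // fall back: try every start, keep the best result found
    for (size_t i = 0; i < starts.size(); ++i) {
      if (i == best) continue;
      GnResult alt = gn(c, y, starts[i], max_iter, grad_tol, step_tol);
      if (alt.obj < res.obj ||
          (alt.converged && !res.converged && alt.obj <= res.obj + 1e-9))
        res = alt;
      if (res.converged) break;
    }
  }
  return res;
}

Ctx make_ctx(NumericVector times, double dose, double cl_typ, double v1t,
             double v2t, double q, double b, NumericVector winv,
             IntegerVector idx) {
  Ctx c;
  c.times = as<std::vector<double> >(times);
  c.dose = dose;
  c.cl_typ = cl_typ; c.v1t = v1t; c.v2t = v2t; c.q = q;
  c.b = b;
  c.winv = as<std::vector<double> >(winv);
  c.idx.resize(idx.size());
  for (int k = 0; k < idx.size(); ++k) c.idx[k] = idx[k] - 1;  // 1- to 0-based
  return c;
}

}  // namespace

// [[Rcpp::export]]
List ebe_solve_cpp(NumericVector y, NumericVector times, double dose,
                   double cl_typ, double v1t, double v2t, double q, double b,
                   NumericVector winv, IntegerVector idx, int max_iter,
                   double grad_tol, double step_tol,
                   Nullable<NumericVector> warm_start = R_NilValue,
                   bool hessian = false) {
  Ctx c = make_ctx(times, dose, cl_typ, v1t, v2t, q, b, winv, idx);
  std::vector<double> yv = as<std::vector<double> >(y);
  const double* warm = NULL;
  std::vector<double> wv;
  if (warm_start.isNotNull()) {
    wv = as<std::vector<double> >(warm_start.get());
    warm = wv.data();
  }
  GnResult res = solve_full(c, yv, max_iter, grad_tol, step_tol, warm);
  List out = List::create(_["eta"] = wrap(res.eta), _["obj"] = res.obj,
                          _["converged"] = res.converged,
                          _["iters"] = res.iters);
  if (hessian) {
    // central-difference Hessian of the MAP objective at the solution
    const int p = (int)c.idx.size();
    const double hh = 1e-4;
    NumericMatrix A(p, p);
    std::vector<double> f(c.times.size());
    const double f0 = map_obj(c, yv, res.eta, f);
    for (int i = 0; i < p; ++i) {
      std::vector<double> e1 = res.eta, e2 = res.eta;
      e1[i] += hh; e2[i] -= hh;
      A(i, i) = (map_obj(c, yv, e1, f) - 2 * f0 + map_obj(c, yv, e2, f)) /
        (hh * hh);
      for (int j = i + 1; j < p; ++j) {
        std::vector<double> pp = res.eta, pm = res.eta, mp = res.eta,
            mm = res.eta;
        pp[i] += hh; pp[j] += hh;
        pm[i] += hh; pm[j] -= hh;
        mp[i] -= hh; mp[j] += hh;
        mm[i] -= hh; mm[j] -= hh;
        A(i, j) = A(j, i) =
          (map_obj(c, yv, pp, f) - map_obj(c, yv, pm, f) -
           map_obj(c, yv, mp, f) + map_obj(c, yv, mm, f)) / (4 * hh * hh);
      }
    }
    out["hessian"] = A;
  }
  return out;
}

// Batch solver for design evaluation: one row of `conc` per simulated
// replicate, `cols` the (1-based) columns forming the design.  Returns a
// matrix with the active eta estimates, the objective and a convergence
// flag per replicate.
// [[Rcpp::export]]
NumericMatrix ebe_batch_cpp(NumericMatrix conc, IntegerVector cols,
                            NumericVector times, double dose, double cl_typ,
                            double v1t, double v2t, double q, double b,
                            NumericVector winv, IntegerVector idx,
                            int max_iter, double grad_tol, double step_tol) {
  Ctx c = make_ctx(times, dose, cl_typ, v1t, v2t, q, b, winv, idx);
  const int n = conc.nrow();
  const int m = cols.size();
  const int p = (int)c.idx.size();
  NumericMatrix out(n, p + 2);
  std::vector<double> y(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) y[j] = conc(i, cols[j] - 1);
    GnResult res = solve_full(c, y, max_iter, grad_tol, step_tol, NULL);
    for (int k = 0; k < p; ++k) out(i, k) = res.eta[k];
    out(i, p) = res.obj;
    out(i, p + 1) = res.converged ? 1.0 : 0.0;
  }
  return out;
}
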