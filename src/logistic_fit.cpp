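#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Logistic growth in log space with the carrying capacity profiled out.
//
// Model: N(t) = K * N0 * exp(r t) / (K + N0 * (exp(r t) - 1)), fit to
// log OD. Reparameterized as log N(t) = log K - log(1 + exp(-r (t - tm)))
// with tm the half-saturation time. For fixed (r, tm) the least-squares
// log K has the closed form mean(y - g), clamped at a liberal cap so that
// simple exponential growth is included as a special (K -> cap) case.

static double prof_sse(double lr, double tm,
                       const double* t, const double* y, int n,
                       double logk_cap, double* logk_out) {
  double r = std::exp(lr);
  std::vector<double> g(n);
  double s = 0.0;
  for (int i = 0; i < n; i++) {
    double z = -r * (t[i] - tm);
    double l1p = (z > 35.0) ? z : std::log1p(std::exp(z));
    g[i] = -l1p;
    s += y[i] - g[i];
  }
  double logk = s / n;
  if (logk > logk_cap) logk = logk_cap;
  double sse = 0.0;
  for (int i = 0; i < n; i++) {
    double e = y[i] - logk - g[i];
    sse += e * e;
  }
  *logk_out = logk;
  return sse;
}

// Nelder-Mead on (log r, tm). Standard reflection/expansion/contraction
// coefficients; converges when the simplex function-value spread is below
// tol relative to the best value.
// [[Rcpp::export]]
List c_fit_logistic_profile(NumericVector t, NumericVector y,
                            double lr0, double tm0, double logk_cap,
                            int maxit = 500, double tol = 1e-12) {
  int n = t.size();
  const double* tp = t.begin();
  const double* yp = y.begin();
  double lk;

  double px[3] = {lr0, lr0 + 0.35, lr0};
  double py[3] = {tm0, tm0, tm0 + 2.0};
  double fv[3];
  for (int i = 0; i < 3; i++)
    fv[i] = prof_sse(px[i], py[i], tp, yp, n, logk_cap, &lk);

  int it = 0;
  bool converged = false;
  for (; it < maxit; it++) {
    // order: b best, w worst, m middle
    int b = 0, w = 0;
    for (int i = 1; i < 3; i++) {
      if (fv[i] < fv[b]) b = i;
      if (fv[i] > fv[w]) w = i;
    }
    if (b == w) { converged = true; break; }
    int m = 3 - b - w;
    if (fv[w] - fv[b] <= tol * std::fabs(fv[b]) + 1e-22) {
      converged = true;
      break;
    }
    double cx = (px[b] + px[m]) / 2.0, cy = (py[b] + py[m]) / 2.0;
    double rx = cx + (cx - px[w]), ry = cy + (cy - py[w]);
    double fr = prof_sse(rx, ry, tp, yp, n, logk_cap, &lk);
    if (fr < fv[b]) {
      double ex = cx + 2.0 * (cx - px[w]), ey = cy + 2.0 * (cy - py[w]);
      double fe = prof_sse(ex, ey, tp, yp, n, logk_cap, &lk);
      if (fe < fr) { px[w] = ex; py[w] = ey; fv[w] = fe; }
      else { px[w] = rx; py[w] = ry; fv[w] = fr; }
    } else if (fr < fv[m]) {
      px[w] = rx; py[w] = ry; fv[w] = fr;
    } else {
      double fref = (fr < fv[w]) ? fr : fv[w];
      double sx = (fr < fv[w]) ? rx : px[w];
      double sy = (fr < fv[w]) ? ry : py[w];
      double kx = cx + 0.5 * (sx - cx), ky = cy + 0.5 * (sy - cy);
      double fk = prof_sse(kx, ky, tp, yp, n, logk_cap, &lk);
      if (fk < fref) { px[w] = kx; py[w] = ky; fv[w] = fk; }
      else { // shrink toward best
        for (int i = 0; i < 3; i++) {
          if (i == b) continue;
          px[i] = px[b] + 0.5 * (px[i] - px[b]);
          py[i] = py[b] + 0.5 * (py[i] - py[b]);
          fv[i] = prof_sse(px[i], py[i], tp, yp, n, logk_cap, &lk);
        }
      }
    }
  }
  int b = 0;
  for (int i = 1; i < 3; i++) if (fv[i] < fv[b]) b = i;
  double sse = prof_sse(px[b], py[b], tp, yp, n, logk_cap, &lk);
  return List::create(
    _["rate"] = std::exp(px[b]),
    _["tm"] = py[b],
    _["log_k"] = lk,
    _["sse"] = sse,
    _["converged"] = converged,
    _["iterations"] = it);
}
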