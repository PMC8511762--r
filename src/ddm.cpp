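#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Wiener first-passage-time density for the simple diffusion model,
// small-time / large-time series with per-evaluation truncation choice
// (Navarro & Fuss 2009 style bounds). All internal computation on the
// s = 1 scale; callers rescale v -> v/s, a -> a/s.

// Standardised lower-boundary density f0(tt, w): a = 1, v = 0, s = 1,
// tt = t / a^2. `err` is the absolute truncation error of the series.
static double f0_std(double tt, double w, double err) {
  if (tt <= 0.0) return 0.0;

  // required number of terms, large-time representation
  double kl;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  // required number of terms, small-time representation
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  double p = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      p += x * std::exp(-x * x / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;  // series truncation can undershoot 0 in far tails
}

// lower-boundary density at decision time t (t excludes non-decision time)
static double wiener_lower(double t, double v, double a, double w,
                           double s, double err) {
  if (t <= 0.0) return 0.0;
  double vn = v / s, an = a / s;
  double tt = t / (an * an);
  return f0_std(tt, w, err) *
         std::exp(-vn * an * w - vn * vn * t / 2.0) / (an * an);
}

// [[Rcpp::export]]
NumericVector fpt_density_cpp(NumericVector t, double v, double a, double w,
                              double s, bool upper, double err) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  for (int i = 0; i < n; ++i) out[i] = wiener_lower(t[i], vv, a, ww, s, err);
  return out;
}

// Summed log density over trials; per-trial drift/threshold vectors allow
// block-indexed parameters. Densities are floored before logging so a stray
// impossible trial produces a large finite penalty.
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector resp,
                      NumericVector v, NumericVector a,
                      double zr, double ter, double s,
                      double floor_, double err) {
  int n = rt.size();
  double ll = 0.0, lfloor = std::log(floor_);
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - ter;
    double d;
    if (resp[i] == 1) {
      d = wiener_lower(t, -v[i], a[i], 1.0 - zr, s, err);
    } else {
      d = wiener_lower(t, v[i], a[i], zr, s, err);
    }
    ll += (d > floor_) ? std::log(d) : lfloor;
  }
  return ll;
}

// Path simulation: Euler-Maruyama with an optional exact Brownian-bridge
// within-step boundary-crossing test. Drift and diffusion are constant, so
// conditional on the step endpoints the path is a Brownian bridge and the
// single-boundary crossing probability exp(-2 d0 d1 / (s^2 dt)) is exact.
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double v, double a, double zr, double ter,
                      double s, double dt, bool bridge, double t_max) {
  NumericVector rt(n);
  IntegerVector resp(n);
  double sq = s * std::sqrt(dt);
  double s2dt = s * s * dt;
  for (int i = 0; i < n; ++i) {
    double x = zr * a, t = 0.0;
    int r = -1;
    while (t < t_max) {
      double x0 = x;
      x += v * dt + sq * norm_rand();
      t += dt;
      if (x >= a) { r = 1; break; }
      if (x <= 0.0) { r = 0; break; }
      if (bridge) {
        double pu = std::exp(-2.0 * (a - x0) * (a - x) / s2dt);
        double pl = std::exp(-2.0 * x0 * x / s2dt);
        double u = unif_rand();
        if (u < pu) { r = 1; break; }
        if (u < pu + pl) { r = 0; break; }
      }
    }
    if (r < 0) r = (x >= zr * a) ? 1 : 0;  // pathological non-absorption guard
    // crossing occurred somewhere inside the final step; centre the record
    double tdec = bridge ? std::max(t - dt / 2.0, dt / 2.0) : t;
    rt[i] = tdec + ter;
    resp[i] = r;
  }
  return List::create(_["rt"] = rt, _["response"] = resp);
}

static inline double rr_obj(double a, double v, double tnd, double s2) {
  double x = v * a / s2;
  double P = 1.0 / (1.0 + std::exp(-x));
  double dtm = (a / (2.0 * v)) * std::tanh(x / 2.0);
  return P / (dtm + tnd);
}

// Reward-rate-optimal threshold at zr = 0.5: coarse scan for a global
// bracket (cheap unimodality guard) followed by golden-section refinement.
// [[Rcpp::export]]
NumericVector optimal_threshold_cpp(NumericVector v, NumericVector ter,
                                    double overhead, double s,
                                    double a_max, double tol) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  const double a_min = 1e-6;
  const int ngrid = 200;
  int n = v.size();
  NumericVector out(n);
  double s2 = s * s;
  for (int i = 0; i < n; ++i) {
    double tnd = ter[i] + overhead;
    double vv = v[i];
    // coarse global scan
    double best = a_min, fbest = rr_obj(a_min, vv, tnd, s2);
    double step = (a_max - a_min) / ngrid;
    int ibest = 0;
    for (int k = 1; k <= ngrid; ++k) {
      double ak = a_min + k * step;
      double fk = rr_obj(ak, vv, tnd, s2);
      if (fk > fbest) { fbest = fk; best = ak; ibest = k; }
    }
    double lo = std::max(a_min, best - step);
    double hi = std::min(a_max, best + step);
    (void)ibest;
    // golden-section maximisation on [lo, hi]
    double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
    double fc = rr_obj(c, vv, tnd, s2), fd = rr_obj(d, vv, tnd, s2);
    while (hi - lo > tol) {
      if (fc > fd) {
        hi = d; d = c; fd = fc;
        c = hi - gr * (hi - lo); fc = rr_obj(c, vv, tnd, s2);
      } else {
        lo = c; c = d; fc = fd;
        d = lo + gr * (hi - lo); fd = rr_obj(d, vv, tnd, s2);
      }
    }
    out[i] = (lo + hi) / 2.0;
  }
  return out;
}
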