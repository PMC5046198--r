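// Constrained null fit for the relative scan statistic.
//
// For a zone Z the null model ties the two series' in-zone probabilities to
// their out-zone probabilities through a shared multiplier k:
//   p_i = k * q_i,  i = 1, 2.
// The null log-likelihood to maximize over (k, q1, q2) is
//   l0 = sum_i [ x_i log(k q_i) + (n_i - x_i) log(1 - k q_i)
//              + (X_i - x_i) log(q_i)
//              + ((N_i - n_i) - (X_i - x_i)) log(1 - q_i) ].
// For fixed k the problem separates per series and is strictly concave in
// q_i on (0, min(1, 1/k)); the stationarity condition reduces to the
// quadratic  k N q^2 - [(N - n + x) + k (X + n - x)] q + X = 0, whose
// smaller root is the feasible maximizer. The profile over k is then
// maximized through its envelope derivative
//   dP/dk = sum_i [ x_i / k - (n_i - x_i) q_i* / (1 - k q_i*) ],
// located by a coarse sign grid plus bisection (cheap: no logarithms per
// iteration). Zones whose conditional maximizer hits the feasibility clamp
// (only possible when a series has x_i = n_i) fall back to a golden-section
// search on the profile itself.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double EPS = 1e-12;
static const double TLO = -20.723265836946411; // log(1e-9)
static const double THI = 20.723265836946411;  // log(1e9)
static const int NGRID = 33;

static inline double xlogy(double a, double p) {
  return a > 0.0 ? a * std::log(p) : 0.0;
}

// Feasible maximizer of the per-series conditional in q for fixed k.
static inline double q_star(double k, double x, double n, double X,
                            double N, bool &clamped) {
  if (X <= 0.0) return 0.0; // every q-weighted count is zero
  double qhi = 1.0 - EPS;
  if (qhi > (1.0 - EPS) / k) qhi = (1.0 - EPS) / k;
  double B = (N - n + x) + k * (X + n - x);
  double A = k * N;
  double q;
  if (A < 1e-300) {
    q = X / B;
  } else {
    double disc = B * B - 4.0 * A * X;
    if (disc < 0.0) disc = 0.0;
    q = 2.0 * X / (B + std::sqrt(disc));
  }
  if (q < EPS) q = EPS;
  if (q > qhi) {
    q = qhi;
    clamped = true;
  }
  return q;
}

// Per-series null log-likelihood contribution at (k, q).
static inline double g_val(double k, double q, double x, double n,
                           double X, double N) {
  if (X <= 0.0) // q -> 0 limit: only the "no success" masses remain
    return xlogy(n - x, 1.0 - k * q) + xlogy((N - n) - (X - x), 1.0 - q);
  double kq = k * q;
  if (kq > 1.0 - EPS) kq = 1.0 - EPS;
  return xlogy(x, kq) + xlogy(n - x, 1.0 - kq) + xlogy(X - x, q) +
         xlogy((N - n) - (X - x), 1.0 - q);
}

struct ZoneData {
  double x1, n1, X1, N1, x2, n2, X2, N2;
};

static inline double profile(double t, const ZoneData &z, double &q1,
                             double &q2, bool &clamped) {
  double k = std::exp(t);
  q1 = q_star(k, z.x1, z.n1, z.X1, z.N1, clamped);
  q2 = q_star(k, z.x2, z.n2, z.X2, z.N2, clamped);
  return g_val(k, q1, z.x1, z.n1, z.X1, z.N1) +
         g_val(k, q2, z.x2, z.n2, z.X2, z.N2);
}

// Envelope derivative of the profile with respect to k (times k > 0 it
// keeps the sign of dP/dt), valid while the conditional maximizers are
// interior.
static inline double dprofile(double t, const ZoneData &z,
                              bool &clamped) {
  double k = std::exp(t);
  double q1 = q_star(k, z.x1, z.n1, z.X1, z.N1, clamped);
  double q2 = q_star(k, z.x2, z.n2, z.X2, z.N2, clamped);
  double d = 0.0;
  if (z.x1 > 0.0) d += z.x1 / k;
  if (z.n1 - z.x1 > 0.0 && q1 > 0.0)
    d -= (z.n1 - z.x1) * q1 / (1.0 - k * q1);
  if (z.x2 > 0.0) d += z.x2 / k;
  if (z.n2 - z.x2 > 0.0 && q2 > 0.0)
    d -= (z.n2 - z.x2) * q2 / (1.0 - k * q2);
  return d;
}

// Golden-section fallback on the profile itself (handles clamped fits).
static void fit_golden(const ZoneData &z, double &t_hat, double &f_hat) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  const int ngrid = 97;
  bool cl = false;
  double q1, q2;
  double best_t = TLO, best_f = -INFINITY;
  for (int i = 0; i < ngrid; ++i) {
    double t = TLO + (THI - TLO) * i / (ngrid - 1);
    double f = profile(t, z, q1, q2, cl);
    if (f > best_f) {
      best_f = f;
      best_t = t;
    }
  }
  double step = (THI - TLO) / (ngrid - 1);
  double a = best_t - step, b = best_t + step;
  if (a < TLO) a = TLO;
  if (b > THI) b = THI;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = profile(c, z, q1, q2, cl), fd = profile(d, z, q1, q2, cl);
  for (int it = 0; it < 90 && (b - a) > 1e-13; ++it) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = profile(c, z, q1, q2, cl);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = profile(d, z, q1, q2, cl);
    }
  }
  t_hat = (fc > fd) ? c : d;
  f_hat = (fc > fd) ? fc : fd;
  if (best_f > f_hat) {
    t_hat = best_t;
    f_hat = best_f;
  }
}

// [[Rcpp::export(name = ".h0_fit_cpp")]]
List h0_fit_cpp(NumericVector x1, NumericVector n1, NumericVector x2,
                NumericVector n2, double X1, double N1, double X2,
                double N2) {
  const int m = x1.size();
  NumericVector k_hat(m), q1_hat(m), q2_hat(m), ll0(m);
  IntegerVector boundary(m);
  const double step = (THI - TLO) / (NGRID - 1);

  for (int iz = 0; iz < m; ++iz) {
    ZoneData z = {x1[iz], n1[iz], X1, N1, x2[iz], n2[iz], X2, N2};
    bool clamped = false;
    double dsign[NGRID];
    for (int i = 0; i < NGRID; ++i)
      dsign[i] = dprofile(TLO + step * i, z, clamped);

    double cand[NGRID + 2];
    int ncand = 0;
    if (dsign[0] <= 0.0) cand[ncand++] = TLO;
    for (int i = 0; i + 1 < NGRID; ++i) {
      if (dsign[i] > 0.0 && dsign[i + 1] <= 0.0) {
        double a = TLO + step * i, b = a + step;
        for (int it = 0; it < 50; ++it) {
          double mid = 0.5 * (a + b);
          if (dprofile(mid, z, clamped) > 0.0) a = mid; else b = mid;
        }
        cand[ncand++] = 0.5 * (a + b);
      }
    }
    if (dsign[NGRID - 1] >= 0.0) cand[ncand++] = THI;

    double t_hat = TLO, f_hat = -INFINITY, q1, q2;
    bool cl2 = false;
    for (int c = 0; c < ncand; ++c) {
      double f = profile(cand[c], z, q1, q2, cl2);
      if (f > f_hat) {
        f_hat = f;
        t_hat = cand[c];
      }
    }
    if (clamped || cl2 || ncand == 0)
      fit_golden(z, t_hat, f_hat);

    bool dummy = false;
    double k = std::exp(t_hat);
    q1_hat[iz] = q_star(k, z.x1, z.n1, z.X1, z.N1, dummy);
    q2_hat[iz] = q_star(k, z.x2, z.n2, z.X2, z.N2, dummy);
    k_hat[iz] = k;
    ll0[iz] = f_hat;
    boundary[iz] = (t_hat - TLO < 1e-8 || THI - t_hat < 1e-8) ? 1 : 0;
  }
  return List::create(_["k"] = k_hat, _["q1"] = q1_hat, _["q2"] = q2_hat,
                      _["ll0"] = ll0, _["boundary"] = boundary);
}
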