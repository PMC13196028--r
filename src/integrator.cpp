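#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monod uptake rate; concentrations clipped to 0 before evaluation so that
// tiny negative solver excursions never produce negative rates.
static inline double monod(double mu_max, double K_S, double C) {
  if (C <= 0.0) return 0.0;
  return mu_max * C / (C + K_S);
}

struct CRModel {
  double mu_g_max, K_S_g, mu_l_max, K_S_l, delta, epsilon;
  int k;
  bool ts_lysate_growth;

  // state layout: y = (C_g, C_l, B_WT, B_TS_1, ..., B_TS_k)
  void rhs(const std::vector<double> &y, std::vector<double> &dy) const {
    const double Cg  = y[0] > 0.0 ? y[0] : 0.0;
    const double Cl  = y[1] > 0.0 ? y[1] : 0.0;
    const double Bwt = y[2] > 0.0 ? y[2] : 0.0;
    const double mug = monod(mu_g_max, K_S_g, Cg);
    const double mul = monod(mu_l_max, K_S_l, Cl);
    const double kd  = k * delta;

    double Bts = 0.0;
    for (int i = 0; i < k; ++i) Bts += (y[3 + i] > 0.0 ? y[3 + i] : 0.0);
    const double Btsk = y[3 + k - 1] > 0.0 ? y[3 + k - 1] : 0.0;

    dy[0] = -mug * (Bwt + Bts);
    dy[1] = -mul * (Bwt + Bts) + epsilon * kd * Btsk;
    dy[2] = (mug + mul) * Bwt;

    // TS compartments: glucose growth always; lysate growth is a model switch
    // (off reproduces the glucose-only chain, lysate uptake then acts as a sink)
    const double gts = mug + (ts_lysate_growth ? mul : 0.0);
    for (int i = 0; i < k; ++i) {
      const double Bi = y[3 + i] > 0.0 ? y[3 + i] : 0.0;
      dy[3 + i] = gts * Bi - kd * Bi;
      if (i > 0) dy[3 + i] += kd * (y[3 + i - 1] > 0.0 ? y[3 + i - 1] : 0.0);
    }
  }
};

// Dormand-Prince 5(4) adaptive step integrator with output forced onto the
// requested time grid. Kept in compiled code because the staged fit and the
// bootstrap evaluate the model tens of thousands of times.
// [[Rcpp::export(name = ".cr_integrate")]]
NumericMatrix cr_integrate(NumericVector times, NumericVector y0,
                           double mu_g_max, double K_S_g,
                           double mu_l_max, double K_S_l,
                           double delta, int k, double epsilon,
                           bool ts_lysate_growth,
                           double rtol, double atol) {
  const int n_out = times.size();
  const int dim = y0.size();
  if (dim != 3 + k)
    stop("state vector length (%d) does not match 3 + k (%d)", dim, 3 + k);
  if (n_out < 2) stop("need at least two output times");

  CRModel m;
  m.mu_g_max = mu_g_max; m.K_S_g = K_S_g;
  m.mu_l_max = mu_l_max; m.K_S_l = K_S_l;
  m.delta = delta; m.k = k; m.epsilon = epsilon;
  m.ts_lysate_growth = ts_lysate_growth;

  // Butcher tableau (Dormand-Prince RK45)
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  NumericMatrix out(n_out, dim);
  std::vector<double> y(y0.begin(), y0.end());
  for (int j = 0; j < dim; ++j) out(0, j) = y[j];

  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), ytmp(dim), ynew(dim);

  double t = times[0];
  double h_next = (times[n_out - 1] - times[0]) / 100.0;
  const double hmin = 1e-14 * std::max(1.0, std::fabs(times[n_out - 1]));
  m.rhs(y, k1);  // FSAL seed
  long n_steps = 0;
  const long max_steps = 20000000L;

  for (int idx = 1; idx < n_out; ++idx) {
    const double t_target = times[idx];
    if (!(t_target > t))
      stop("output times must be strictly increasing");
    while (t < t_target) {
      if (++n_steps > max_steps)
        stop("integration failed: step budget exhausted at t = %g", t);
      bool hit = false;
      double h = h_next;
      if (t + h >= t_target) { h = t_target - t; hit = true; }

      for (int j = 0; j < dim; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      m.rhs(ytmp, k2);
      for (int j = 0; j < dim; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      m.rhs(ytmp, k3);
      for (int j = 0; j < dim; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      m.rhs(ytmp, k4);
      for (int j = 0; j < dim; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      m.rhs(ytmp, k5);
      for (int j = 0; j < dim; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      m.rhs(ytmp, k6);
      for (int j = 0; j < dim; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      m.rhs(ynew, k7);

      double err = 0.0;
      for (int j = 0; j < dim; ++j) {
        const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                               e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double sc =
            atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        const double r = ej / sc;
        err += r * r;
      }
      err = std::sqrt(err / dim);

      if (err <= 1.0) {  // accept
        t = hit ? t_target : t + h;
        y = ynew;
        std::swap(k1, k7);  // FSAL
        double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        // a step truncated to hit the grid says nothing about accuracy limits
        if (!hit) h_next = h * fac;
      } else {  // reject
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.2) fac = 0.2;
        h_next = h * fac;
        if (h_next < hmin)
          stop("integration failed: step size collapsed at t = %g", t);
      }
    }
    for (int j = 0; j < dim; ++j) out(idx, j) = y[j];
  }
  return out;
}
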