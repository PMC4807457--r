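// Hodgkin-Huxley membrane/gating dynamics with an adaptive Dormand-Prince
// 5(4) integrator and 5th-order dense output.  All voltages are in the
// original HH sign convention (V = displacement from rest, depolarization
// negative); time in ms, conductances in mS/cm^2, currents in uA/cm^2.
//
// The compiled layer exists because ABC-SMC needs ~1e5 trace simulations per
// fit; the R layer owns all bookkeeping and exposes the same model algebra
// for oracle-style cross-checks.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// exp with argument clamped to +/-500: exp overflows near 709 and nothing
// physiological gets within two orders of magnitude of that bound.
static inline double safe_exp(double x) {
  if (x > 500.0) x = 500.0;
  if (x < -500.0) x = -500.0;
  return std::exp(x);
}

// k1*(V + k2)/(exp((V + k2)/k3) - 1) with the removable singularity at
// V = -k2 replaced by its analytic limit k1*k3 inside a small guard band.
static inline double alpha_form(double k1, double k2, double k3, double V) {
  const double u = V + k2;
  if (std::fabs(u) < 1e-7 * k3) return k1 * k3;
  return k1 * u / (safe_exp(u / k3) - 1.0);
}

// Voltage-dependency parameter order (matches R side):
//  0 k_an1, 1 k_an2, 2 k_an3, 3 k_bn1, 4 k_bn2,
//  5 k_am1, 6 k_am2, 7 k_am3, 8 k_bm1, 9 k_bm2,
// 10 k_ah1, 11 k_ah2, 12 k_bh1, 13 k_bh2
// Rate order: an, bn, am, bm, ah, bh
static inline void rates_at(const double* k, double V, double* r) {
  r[0] = alpha_form(k[0], k[1], k[2], V);
  r[1] = k[3] * safe_exp(V / k[4]);
  r[2] = alpha_form(k[5], k[6], k[7], V);
  r[3] = k[8] * safe_exp(V / k[9]);
  r[4] = k[10] * safe_exp(V / k[11]);
  r[5] = 1.0 / (safe_exp((V + k[12]) / k[13]) + 1.0);
}

// [[Rcpp::export(name = ".hh_rates_cpp")]]
NumericVector hh_rates_cpp(NumericVector k, double V) {
  double r[6];
  rates_at(REAL(k), V, r);
  return NumericVector::create(r[0], r[1], r[2], r[3], r[4], r[5]);
}

struct HHSys {
  const double* k;      // 14 voltage-dependency params (rates_mode == 0)
  const double* rates;  // 6 fixed rates (rates_mode == 1)
  int rates_mode;
  // membrane constants: C_M, gbar_K, gbar_Na, g_l, V_Na, V_K, V_l
  double CM, gK, gNa, gl, VNa, VK, Vl;
  // current segment drive
  int mode;      // 0 clamp_V, 1 clamp_I, 2 free
  double drive;  // clamp voltage or applied current

  void rhs(const double* y, double* dy) const {
    const double V = y[0], n = y[1], m = y[2], h = y[3];
    double r[6];
    if (rates_mode) {
      for (int i = 0; i < 6; ++i) r[i] = rates[i];
    } else {
      rates_at(k, V, r);
    }
    dy[1] = r[0] * (1.0 - n) - r[1] * n;
    dy[2] = r[2] * (1.0 - m) - r[3] * m;
    dy[3] = r[4] * (1.0 - h) - r[5] * h;
    if (mode == 0) {
      dy[0] = 0.0;
    } else {
      const double gNa_t = gNa * m * m * m * h;
      const double gK_t = gK * n * n * n * n;
      const double Ii = gNa_t * (V - VNa) + gK_t * (V - VK) + gl * (V - Vl);
      const double Iapp = (mode == 1) ? drive : 0.0;
      dy[0] = (Iapp - Ii) / CM;
    }
  }
};

// Dormand-Prince 5(4) coefficients
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
// dense-output coefficients (Hairer & Wanner DOPRI5 CONTD5)
static const double d1 = -12715105075.0 / 11282082432.0,
                    d3 = 87487479700.0 / 32700410799.0,
                    d4 = -10690763975.0 / 1880347072.0,
                    d5 = 701980252875.0 / 199316789632.0,
                    d6 = -1453857185.0 / 822651844.0,
                    d7 = 69997945.0 / 29380423.0;

#define NS 4

struct Dopri {
  HHSys sys;
  double rtol, atol;
  // dense-output polynomial for the last accepted step
  double rc1[NS], rc2[NS], rc3[NS], rc4[NS], rc5[NS];
  double t_old, h_old;

  void dense_eval(double t, double* out) const {
    const double th = (t - t_old) / h_old;
    const double th1 = 1.0 - th;
    for (int i = 0; i < NS; ++i)
      out[i] = rc1[i] +
               th * (rc2[i] + th1 * (rc3[i] + th * (rc4[i] + th1 * rc5[i])));
  }

  // Integrate y from t0 to t1, writing dense samples at grid times strictly
  // before t1 (samples at t1 belong to the next segment, after any
  // instantaneous reset, or to the final flush).  Returns false on
  // step-size collapse.
  bool integrate(double t0, double t1, double* y, const double* tg, int ntg,
                 int& ig, double* samp, int nrow, int scol) {
    if (t1 <= t0) return true;
    double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS], ytmp[NS],
        ynew[NS];
    double t = t0;
    sys.rhs(y, k1);
    // initial step guess
    double h = 0.01;
    if (h > t1 - t0) h = t1 - t0;
    long nstep = 0;
    while (t < t1) {
      if (++nstep > 10000000L) return false;
      if (h < 1e-12) return false;
      if (t + h > t1) h = t1 - t;
      for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      sys.rhs(ytmp, k2);
      for (int i = 0; i < NS; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      sys.rhs(ytmp, k3);
      for (int i = 0; i < NS; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      sys.rhs(ytmp, k4);
      for (int i = 0; i < NS; ++i)
        ytmp[i] =
            y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      sys.rhs(ytmp, k5);
      for (int i = 0; i < NS; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      sys.rhs(ytmp, k6);
      for (int i = 0; i < NS; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      sys.rhs(ynew, k7);
      // embedded error estimate
      double err = 0.0;
      for (int i = 0; i < NS; ++i) {
        const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc =
            atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double q = ei / sc;
        err += q * q;
      }
      err = std::sqrt(err / NS);
      if (!std::isfinite(err)) return false;
      if (err <= 1.0) {
        // accept; build dense interpolant and emit samples in (t, t+h]
        t_old = t;
        h_old = h;
        for (int i = 0; i < NS; ++i) {
          const double ydiff = ynew[i] - y[i];
          const double bspl = h * k1[i] - ydiff;
          rc1[i] = y[i];
          rc2[i] = ydiff;
          rc3[i] = bspl;
          rc4[i] = ydiff - h * k7[i] - bspl;
          rc5[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                        d6 * k6[i] + d7 * k7[i]);
        }
        const double tnew = t + h;
        double yi[NS];
        while (ig < ntg && tg[ig] <= tnew + 1e-12 && tg[ig] < t1 - 1e-12) {
          dense_eval(tg[ig], yi);
          for (int i = 0; i < NS; ++i) samp[ig + nrow * (scol + i)] = yi[i];
          ++ig;
        }
        t = tnew;
        for (int i = 0; i < NS; ++i) {
          y[i] = ynew[i];
          k1[i] = k7[i];  // FSAL
        }
      }
      // step-size controller
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    return true;
  }
};

// Simulate over a piecewise drive schedule.
//
// params: 14 k-values (rates_mode = 0) or 6 fixed rates (rates_mode = 1)
// consts: C_M, gbar_K, gbar_Na, g_l, V_Na, V_K, V_l
// segments: matrix with columns (t0, t1, mode, value, v_set, v_add);
//   mode 0 = clamp_V (value = clamp voltage), 1 = clamp_I (value = applied
//   current), 2 = free-running; v_set (NaN = skip) resets V at segment
//   start, then v_add is added; clamp_V then overrides V with its value.
// t_grid: strictly increasing sample times within [segments t0, t1].
// y0: initial (V, n, m, h).
//
// Returns t_grid x 4 matrix (V, n, m, h), or stops with an error condition
// of class "hh_integration_error" on solver failure.
// [[Rcpp::export(name = ".hh_simulate_cpp")]]
NumericMatrix hh_simulate_cpp(NumericVector params, int rates_mode,
                              NumericVector consts, NumericMatrix segments,
                              NumericVector t_grid, NumericVector y0,
                              double rtol, double atol) {
  const int ntg = t_grid.size();
  NumericMatrix out(ntg, NS);
  Dopri stepper;
  stepper.rtol = rtol;
  stepper.atol = atol;
  HHSys& S = stepper.sys;
  S.rates_mode = rates_mode;
  if (rates_mode) {
    S.rates = REAL(params);
    S.k = nullptr;
  } else {
    S.k = REAL(params);
    S.rates = nullptr;
  }
  S.CM = consts[0];
  S.gK = consts[1];
  S.gNa = consts[2];
  S.gl = consts[3];
  S.VNa = consts[4];
  S.VK = consts[5];
  S.Vl = consts[6];

  double y[NS] = {y0[0], y0[1], y0[2], y0[3]};
  const double* tg = REAL(t_grid);
  double* samp = REAL(out);
  int ig = 0;
  const int nseg = segments.nrow();
  for (int s = 0; s < nseg; ++s) {
    const double t0 = segments(s, 0), t1 = segments(s, 1);
    S.mode = (int)segments(s, 2);
    S.drive = segments(s, 3);
    const double vset = segments(s, 4), vadd = segments(s, 5);
    if (R_finite(vset)) y[0] = vset;
    if (R_finite(vadd)) y[0] += vadd;
    if (S.mode == 0) y[0] = S.drive;
    // samples exactly at segment start reflect the post-reset state
    while (ig < ntg && tg[ig] <= t0 + 1e-12) {
      for (int i = 0; i < NS; ++i) samp[ig + ntg * i] = y[i];
      ++ig;
    }
    bool ok = stepper.integrate(t0, t1, y, tg, ntg, ig, samp, ntg, 0);
    if (!ok) stop("hh_integration_error: solver failed in segment %d", s + 1);
    if (S.mode == 0) {
      // clamped V is exact by construction; remove interpolation fuzz
      for (int j = 0; j < ig; ++j)
        if (tg[j] > t0 - 1e-12 && tg[j] <= t1 + 1e-12) samp[j] = S.drive;
      y[0] = S.drive;
    }
  }
  // any trailing samples at/after final time
  while (ig < ntg) {
    for (int i = 0; i < NS; ++i) samp[ig + ntg * i] = y[i];
    ++ig;
  }
  return out;
}

// Batched voltage-clamp conductance traces: the ABC-SMC hot path.
// For each depolarization d, clamp V = -d over [0, duration] from y0 and
// return g_K (columns 1..M) and g_Na (columns M+1..2M) sampled on t_grid.
// [[Rcpp::export(name = ".hh_clamp_batch_cpp")]]
NumericMatrix hh_clamp_batch_cpp(NumericVector params, int rates_mode,
                                 NumericVector consts,
                                 NumericVector depolarizations,
                                 NumericVector t_grid, NumericVector y0,
                                 double rtol, double atol) {
  const int ntg = t_grid.size();
  const int M = depolarizations.size();
  NumericMatrix out(ntg, 2 * M);
  const double gbarK = consts[1], gbarNa = consts[2];
  Dopri stepper;
  stepper.rtol = rtol;
  stepper.atol = atol;
  HHSys& S = stepper.sys;
  S.rates_mode = rates_mode;
  if (rates_mode) {
    S.rates = REAL(params);
    S.k = nullptr;
  } else {
    S.k = REAL(params);
    S.rates = nullptr;
  }
  S.CM = consts[0];
  S.gK = consts[1];
  S.gNa = consts[2];
  S.gl = consts[3];
  S.VNa = consts[4];
  S.VK = consts[5];
  S.Vl = consts[6];
  S.mode = 0;
  const double* tg = REAL(t_grid);
  const double tend = tg[ntg - 1];
  std::vector<double> buf(ntg * NS);
  for (int j = 0; j < M; ++j) {
    S.drive = -depolarizations[j];
    double y[NS] = {S.drive, y0[1], y0[2], y0[3]};
    int ig = 0;
    // emit t = 0 samples directly
    while (ig < ntg && tg[ig] <= 1e-12) {
      for (int i = 0; i < NS; ++i) buf[ig + ntg * i] = y[i];
      ++ig;
    }
    bool ok =
        stepper.integrate(0.0, tend, y, tg, ntg, ig, buf.data(), ntg, 0);
    if (!ok)
      stop("hh_integration_error: clamp solver failed at depolarization %g",
           depolarizations[j]);
    while (ig < ntg) {
      for (int i = 0; i < NS; ++i) buf[ig + ntg * i] = y[i];
      ++ig;
    }
    for (int r = 0; r < ntg; ++r) {
      const double n = buf[r + ntg], m = buf[r + 2 * ntg],
                   h = buf[r + 3 * ntg];
      out(r, j) = gbarK * n * n * n * n;
      out(r, M + j) = gbarNa * m * m * m * h;
    }
  }
  return out;
}
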