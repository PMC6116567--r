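// Adaptive Dormand-Prince 5(4) integration of the three-state closure
// (vascular tone mu, tissue O2, oxidised CuA fraction a) driven by
// piecewise-linear input channels sampled on the output grid.
//
// The right-hand side here must stay algebraically identical to the pure-R
// reference in R/model_core.R; the test suite cross-checks the two.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double P_a_n, PaCO2_n, O2t_n, R_P, R_C, R_O, R_u, tau_mu, k_r, r_n;
  double K_flow, P_ic_n, CBF_n, Hbtot, CMRO2_n, k_m, K_mO2;
  double kappa_O2, D_O2, sigma_O2, k_CuA, k_red_ratio, g_n;
  bool clamp;
};

struct InputGrid {
  const double *t;
  const double *Pa, *SaO2, *PaCO2, *u, *m;
  int n;
  // linear interpolation; constant extrapolation at the ends
  void at(double tq, double out[5]) const {
    if (tq <= t[0]) {
      out[0] = Pa[0]; out[1] = SaO2[0]; out[2] = PaCO2[0];
      out[3] = u[0]; out[4] = m[0]; return;
    }
    if (tq >= t[n - 1]) {
      int k = n - 1;
      out[0] = Pa[k]; out[1] = SaO2[k]; out[2] = PaCO2[k];
      out[3] = u[k]; out[4] = m[k]; return;
    }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (t[mid] <= tq) lo = mid; else hi = mid;
    }
    double w = (tq - t[lo]) / (t[hi] - t[lo]);
    out[0] = Pa[lo] + w * (Pa[hi] - Pa[lo]);
    out[1] = SaO2[lo] + w * (SaO2[hi] - SaO2[lo]);
    out[2] = PaCO2[lo] + w * (PaCO2[hi] - PaCO2[lo]);
    out[3] = u[lo] + w * (u[hi] - u[lo]);
    out[4] = m[lo] + w * (m[hi] - m[lo]);
  }
};

// returns false when the oxygen supply is exhausted (SvO2 < 0 or CBF <= 0)
bool rhs(double tq, const double y[3], const InputGrid &in, const Pars &p,
         double dy[3]) {
  double inp[5];
  in.at(tq, inp);
  const double Pa = inp[0], SaO2 = inp[1], PaCO2 = inp[2], u = inp[3],
               m = inp[4];
  const double mu = y[0], O2t = y[1], a = y[2];
  const double g = O2t / (O2t + p.K_mO2);
  const double grel = g / p.g_n;
  const double CMRO2 = p.CMRO2_n * (1.0 + p.k_m * (u - 1.0)) * grel;
  const double r = p.r_n * (1.0 - p.k_r * mu) * m;
  const double r2 = r * r;
  const double CBF_flow = p.K_flow * r2 * r2 * (Pa - p.P_ic_n);
  const double CBF = p.clamp ? p.CBF_n : CBF_flow;
  if (CBF <= 0.0) return false;
  const double SvO2 = SaO2 - CMRO2 / (CBF * p.Hbtot);
  if (SvO2 < 0.0) return false;
  const double Sc = 0.5 * (SaO2 + SvO2);
  const double eta = p.R_P * (Pa / p.P_a_n - 1.0) +
                     p.R_C * (1.0 - PaCO2 / p.PaCO2_n) +
                     p.R_O * (O2t / p.O2t_n - 1.0) + p.R_u * (1.0 - u);
  dy[0] = (std::tanh(eta) - mu) / p.tau_mu;
  dy[1] = p.kappa_O2 *
          (p.D_O2 * (Sc * p.Hbtot - p.sigma_O2 * O2t) - CMRO2);
  dy[2] = p.k_CuA * (grel * (1.0 - a) - p.k_red_ratio * u * a);
  return true;
}

} // namespace

// [[Rcpp::export(name = ".nh_integrate_cpp")]]
List nh_integrate_cpp(NumericVector time, NumericVector Pa, NumericVector SaO2,
                      NumericVector PaCO2, NumericVector u, NumericVector m,
                      bool clamp, List pars, NumericVector y0, double rtol,
                      double atol) {
  const int n = time.size();
  Pars p;
  p.P_a_n = as<double>(pars["P_a_n"]);
  p.PaCO2_n = as<double>(pars["PaCO2_n"]);
  p.O2t_n = as<double>(pars["O2t_n"]);
  p.R_P = as<double>(pars["R_P"]);
  p.R_C = as<double>(pars["R_C"]);
  p.R_O = as<double>(pars["R_O"]);
  p.R_u = as<double>(pars["R_u"]);
  p.tau_mu = as<double>(pars["tau_mu"]);
  p.k_r = as<double>(pars["k_r"]);
  p.r_n = as<double>(pars["r_n"]);
  p.K_flow = as<double>(pars["K_flow"]);
  p.P_ic_n = as<double>(pars["P_ic_n"]);
  p.CBF_n = as<double>(pars["CBF_n"]);
  p.Hbtot = as<double>(pars["Hbtot"]);
  p.CMRO2_n = as<double>(pars["CMRO2_n"]);
  p.k_m = as<double>(pars["k_m"]);
  p.K_mO2 = as<double>(pars["K_mO2"]);
  p.kappa_O2 = as<double>(pars["kappa_O2"]);
  p.D_O2 = as<double>(pars["D_O2"]);
  p.sigma_O2 = as<double>(pars["sigma_O2"]);
  p.k_CuA = as<double>(pars["k_CuA"]);
  p.k_red_ratio = as<double>(pars["k_red_ratio"]);
  p.g_n = as<double>(pars["g_n"]);
  p.clamp = clamp;

  InputGrid in;
  in.t = REAL(time); in.Pa = REAL(Pa); in.SaO2 = REAL(SaO2);
  in.PaCO2 = REAL(PaCO2); in.u = REAL(u); in.m = REAL(m); in.n = n;

  NumericMatrix states(n, 3);
  double y[3] = {y0[0], y0[1], y0[2]};
  states(0, 0) = y[0]; states(0, 1) = y[1]; states(0, 2) = y[2];

  // Dormand-Prince coefficients
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
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
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  double t = time[0];
  double h = std::min(0.05, (time[n - 1] - time[0]) / 10.0);
  const double hmin = 1e-10;
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], y5[3];
  bool have_k1 = rhs(t, y, in, p, k1);
  if (!have_k1) {
    return List::create(_["success"] = false, _["t_fail"] = t,
                        _["states"] = states,
                        _["message"] = "oxygen supply exhausted");
  }

  for (int iout = 1; iout < n; ++iout) {
    const double t_end = time[iout];
    while (t < t_end) {
      if (h > t_end - t) h = t_end - t;
      if (h < hmin) h = hmin;
      bool ok = true;
      for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      ok = ok && rhs(t + c2 * h, ytmp, in, p, k2);
      if (ok) {
        for (int i = 0; i < 3; ++i)
          ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        ok = rhs(t + c3 * h, ytmp, in, p, k3);
      }
      if (ok) {
        for (int i = 0; i < 3; ++i)
          ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        ok = rhs(t + c4 * h, ytmp, in, p, k4);
      }
      if (ok) {
        for (int i = 0; i < 3; ++i)
          ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
        ok = rhs(t + c5 * h, ytmp, in, p, k5);
      }
      if (ok) {
        for (int i = 0; i < 3; ++i)
          ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
        ok = rhs(t + h, ytmp, in, p, k6);
      }
      if (ok) {
        for (int i = 0; i < 3; ++i)
          y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
        ok = rhs(t + h, y5, in, p, k7);
      }
      if (!ok) {
        // a trial evaluation left the oxygen-feasible region: shrink the
        // step; below hmin the trajectory itself is infeasible
        if (h <= 2 * hmin) {
          return List::create(_["success"] = false, _["t_fail"] = t,
                              _["states"] = states,
                              _["message"] = "oxygen supply exhausted");
        }
        h *= 0.25;
        continue;
      }
      double err = 0.0;
      for (int i = 0; i < 3; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double q = ei / sc;
        err += q * q;
      }
      err = std::sqrt(err / 3.0);
      if (err <= 1.0 || h <= 2 * hmin) {
        t += h;
        for (int i = 0; i < 3; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      }
      double fac = 0.9 * std::pow(err > 1e-14 ? err : 1e-14, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    states(iout, 0) = y[0]; states(iout, 1) = y[1]; states(iout, 2) = y[2];
  }
  return List::create(_["success"] = true, _["t_fail"] = NA_REAL,
                      _["states"] = states, _["message"] = "");
}
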