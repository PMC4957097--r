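// Osmotic actuator transport ODE (Kedem-Katchalsky form) with optional
// mass-action complex coupling, integrated by adaptive Cash-Karp RK45 or
// fixed-step RK4. State vector: y = (V [m^3], N_1..N_n [mol]).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ActPars {
  int n;
  std::vector<double> gamma, sigma, Ps;
  double S, alpha, kBD, V0, RT;
  bool turgor;
  double K;              // association constant, (L/mol)^3; 0 disables
  int iK, iGlc, iGln;    // 0-based solute indices of KCl, D-Glc, L-Gln
};

// Bisection for x = K * (tK - x)^2 * (tG - x) * (tQ - x), concentrations
// in mol/L; the salt supplies both ions at its molarity so the two ionic
// factors coincide.
double solve_extent4(double tK, double tG, double tQ, double K) {
  double hi = std::min(tK, std::min(tG, tQ));
  if (K <= 0.0 || hi <= 0.0) return 0.0;
  double lo = 0.0;
  for (int it = 0; it < 100; ++it) {
    double x = 0.5 * (lo + hi);
    double f = x - K * (tK - x) * (tK - x) * (tG - x) * (tQ - x);
    if (f > 0.0) hi = x; else lo = x;
    if (hi - lo <= 1e-14 * hi) break;
  }
  return 0.5 * (lo + hi);
}

void rhs(const double* y, double* dy, const ActPars& p) {
  double V = y[0];
  std::vector<double> c(p.n), cf(p.n);
  for (int k = 0; k < p.n; ++k) c[k] = y[1 + k] / V;  // mol/m^3
  double x = 0.0;                                      // complex, mol/m^3
  if (p.K > 0.0 && p.iK >= 0) {
    x = 1000.0 * solve_extent4(c[p.iK] / 1000.0, c[p.iGlc] / 1000.0,
                               c[p.iGln] / 1000.0, p.K);
  }
  double drive = 0.0;
  for (int k = 0; k < p.n; ++k) {
    cf[k] = c[k];
    if (x > 0.0 && (k == p.iK || k == p.iGlc || k == p.iGln)) cf[k] -= x;
    if (cf[k] < 0.0) cf[k] = 0.0;
    drive += p.sigma[k] * p.gamma[k] * cf[k];
  }
  drive += x;  // complex: sigma = 1, one ideal particle
  double P = p.turgor ? p.kBD * (V - p.V0) / p.V0 : 0.0;
  double dV = p.S * p.alpha * (p.RT * drive - P);
  dy[0] = dV;
  for (int k = 0; k < p.n; ++k)
    dy[1 + k] = -p.Ps[k] * p.S * cf[k] - (1.0 - p.sigma[k]) * cf[k] * dV;
}

// Cash-Karp embedded RK45 coefficients.
const double b21 = 1.0 / 5.0;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
             b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
             b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
             b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
             c6 = 512.0 / 1771.0;
const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
             d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
             d6 = c6 - 1.0 / 4.0;

// One Cash-Karp step; returns max scaled error.
double ck_step(const std::vector<double>& y, std::vector<double>& yout,
               double h, const ActPars& p, const std::vector<double>& dydx) {
  int m = (int)y.size();
  std::vector<double> k2(m), k3(m), k4(m), k5(m), k6(m), yt(m);
  for (int i = 0; i < m; ++i) yt[i] = y[i] + h * b21 * dydx[i];
  rhs(yt.data(), k2.data(), p);
  for (int i = 0; i < m; ++i)
    yt[i] = y[i] + h * (b31 * dydx[i] + b32 * k2[i]);
  rhs(yt.data(), k3.data(), p);
  for (int i = 0; i < m; ++i)
    yt[i] = y[i] + h * (b41 * dydx[i] + b42 * k2[i] + b43 * k3[i]);
  rhs(yt.data(), k4.data(), p);
  for (int i = 0; i < m; ++i)
    yt[i] = y[i] + h * (b51 * dydx[i] + b52 * k2[i] + b53 * k3[i] +
                        b54 * k4[i]);
  rhs(yt.data(), k5.data(), p);
  for (int i = 0; i < m; ++i)
    yt[i] = y[i] + h * (b61 * dydx[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  rhs(yt.data(), k6.data(), p);
  double errmax = 0.0;
  for (int i = 0; i < m; ++i) {
    yout[i] = y[i] + h * (c1 * dydx[i] + c3 * k3[i] + c4 * k4[i] +
                          c6 * k6[i]);
    double erri = h * (d1 * dydx[i] + d3 * k3[i] + d4 * k4[i] +
                       d5 * k5[i] + d6 * k6[i]);
    double scale = std::fabs(y[i]) + std::fabs(h * dydx[i]) + 1e-30;
    errmax = std::max(errmax, std::fabs(erri) / scale);
  }
  return errmax;
}

void rk4_step(std::vector<double>& y, double h, const ActPars& p) {
  int m = (int)y.size();
  std::vector<double> k1(m), k2(m), k3(m), k4(m), yt(m);
  rhs(y.data(), k1.data(), p);
  for (int i = 0; i < m; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(yt.data(), k2.data(), p);
  for (int i = 0; i < m; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(yt.data(), k3.data(), p);
  for (int i = 0; i < m; ++i) yt[i] = y[i] + h * k3[i];
  rhs(yt.data(), k4.data(), p);
  for (int i = 0; i < m; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

ActPars unpack(List pars) {
  ActPars p;
  NumericVector g = pars["gamma"], s = pars["sigma"], ps = pars["Ps"];
  p.n = g.size();
  p.gamma.assign(g.begin(), g.end());
  p.sigma.assign(s.begin(), s.end());
  p.Ps.assign(ps.begin(), ps.end());
  p.S = as<double>(pars["S"]);
  p.alpha = as<double>(pars["alpha"]);
  p.kBD = as<double>(pars["kBD"]);
  p.V0 = as<double>(pars["V0"]);
  p.RT = as<double>(pars["RT"]);
  p.turgor = as<bool>(pars["turgor"]);
  p.K = as<double>(pars["K"]);
  IntegerVector idx = pars["idx"];  // 0-based (KCl, D-Glc, L-Gln) or -1
  p.iK = idx[0]; p.iGlc = idx[1]; p.iGln = idx[2];
  return p;
}

void check_finite(const std::vector<double>& y) {
  for (double v : y)
    if (!std::isfinite(v)) stop("non-finite state during integration");
  if (y[0] <= 0.0) stop("chamber volume became non-positive");
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix actuator_integrate_cpp(NumericVector y0,
                                     NumericVector sample_times,
                                     List pars, double rtol,
                                     std::string method, double h_fixed) {
  ActPars p = unpack(pars);
  int m = y0.size(), ns = sample_times.size();
  if (m != p.n + 1) stop("state length does not match parameter vectors");
  std::vector<double> y(y0.begin(), y0.end());
  NumericMatrix out(ns, m + 1);
  double t = 0.0;
  int isamp = 0;
  // emit any sample at t = 0
  while (isamp < ns && sample_times[isamp] <= 0.0) {
    out(isamp, 0) = sample_times[isamp];
    for (int i = 0; i < m; ++i) out(isamp, 1 + i) = y[i];
    ++isamp;
  }
  double t_end = sample_times[ns - 1];
  bool adaptive = (method == "rk45");
  double h = adaptive ? std::max(t_end * 1e-6, 1e-9) : h_fixed;
  if (!adaptive && h_fixed <= 0.0) stop("fixed-step method needs h > 0");
  std::vector<double> dydx(m), ynew(m);
  while (isamp < ns) {
    double t_next = sample_times[isamp];
    double hstep = std::min(h, t_next - t);
    if (adaptive) {
      rhs(y.data(), dydx.data(), p);
      for (;;) {
        double err = ck_step(y, ynew, hstep, p, dydx) / rtol;
        if (err <= 1.0) {
          t += hstep;
          y = ynew;
          // grow for the next step (from the un-truncated h)
          double grow = (err > 1e-8) ? 0.9 * std::pow(err, -0.2) : 5.0;
          h = std::min(hstep * std::min(grow, 5.0), t_end);
          break;
        }
        hstep *= std::max(0.9 * std::pow(err, -0.25), 0.1);
        if (hstep < 1e-12 * std::max(t_end, 1.0))
          stop("step-size underflow in adaptive integration");
      }
    } else {
      rk4_step(y, hstep, p);
      t += hstep;
    }
    check_finite(y);
    while (isamp < ns && t >= sample_times[isamp] - 1e-9 * std::max(t, 1.0)) {
      out(isamp, 0) = sample_times[isamp];
      for (int i = 0; i < m; ++i) out(isamp, 1 + i) = y[i];
      ++isamp;
    }
  }
  return out;
}

// [[Rcpp::export]]
double solve_extent4_cpp(double tK, double tG, double tQ, double K) {
  return solve_extent4(tK, tG, tQ, K);
}
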