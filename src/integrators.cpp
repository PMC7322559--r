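#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrators for the two dynamical systems in the package:
// the canonical-microcircuit (CMC) neural mass model and the Balloon
// haemodynamic model.  Both are called many times inside variational Laplace
// (finite-difference gradients), so they are compiled.

namespace {

inline double sigm(double v) {
  // centred logistic: zero at rest, range (-1/2, 1/2)
  return 1.0 / (1.0 + std::exp(-v)) - 0.5;
}

// Intrinsic gain indexing (13 connections per region), order:
//  0 ss->ss  1 sp->ss  2 ii->ss
//  3 sp->sp  4 ss->sp  5 ii->sp
//  6 ii->ii  7 dp->ii  8 ss->ii  9 sp->ii
// 10 dp->dp 11 ii->dp 12 sp->dp
struct CMCSys {
  int R;
  const double* kap;    // 4
  const double* g;      // 13 x R, column-major
  const double* Af;     // R x R, gain of forward edge j -> k at (k, j)
  const double* Ab;     // R x R
  const double* C;      // R
  double onset, disp;
  mutable std::vector<double> s;  // firing-rate buffer (4 * R)

  double input(double t) const {
    double x = (t - onset) / disp;
    return std::exp(-0.5 * x * x);
  }

  // state: for each region k, 4 potentials then 4 velocities are interleaved
  // as x[k*8 + p] = V_p, x[k*8 + 4 + p] = dV_p/dt, p in (ss, sp, ii, dp)
  void deriv(double t, const double* x, double* dx,
             double* exc = nullptr, double* inh = nullptr,
             double* ext = nullptr, double* inp = nullptr) const {
    const double u = input(t);
    // firing rates of all populations in all regions
    if ((int)s.size() != 4 * R) s.resize(4 * R);
    for (int k = 0; k < R; ++k)
      for (int p = 0; p < 4; ++p) s[k * 4 + p] = sigm(x[k * 8 + p]);
    for (int k = 0; k < R; ++k) {
      const double* gk = g + 13 * k;
      // extrinsic afferents (A-weighted distal firing)
      double ef = 0.0, eb = 0.0;
      for (int j = 0; j < R; ++j) {
        ef += Af[k + R * j] * s[j * 4 + 1];  // distal sp
        eb += Ab[k + R * j] * s[j * 4 + 3];  // distal dp
      }
      const double sss = s[k * 4 + 0], ssp = s[k * 4 + 1];
      const double sii = s[k * 4 + 2], sdp = s[k * 4 + 3];
      double fe[4], fi[4], fx[4], fu[4];
      // ss: forward extrinsic - self - sp - ii + C u
      fe[0] = -gk[1] * ssp;
      fi[0] = -gk[0] * sss - gk[2] * sii;
      fx[0] = ef;
      fu[0] = C[k] * u;
      // sp: backward extrinsic - self + ss - ii
      fe[1] = gk[4] * sss;
      fi[1] = -gk[3] * ssp - gk[5] * sii;
      fx[1] = eb;
      fu[1] = 0.0;
      // ii: backward extrinsic - self - dp + ss + sp
      fe[2] = -gk[7] * sdp + gk[8] * sss + gk[9] * ssp;
      fi[2] = -gk[6] * sii;
      fx[2] = eb;
      fu[2] = 0.0;
      // dp: forward extrinsic - self - ii + sp
      fe[3] = gk[12] * ssp;
      fi[3] = -gk[10] * sdp - gk[11] * sii;
      fx[3] = ef;
      fu[3] = 0.0;
      for (int p = 0; p < 4; ++p) {
        const double f = fe[p] + fi[p] + fx[p] + fu[p];
        const double V = x[k * 8 + p], W = x[k * 8 + 4 + p];
        dx[k * 8 + p] = W;
        dx[k * 8 + 4 + p] = kap[p] * kap[p] * (f - V) - 2.0 * kap[p] * W;
        if (exc) {
          exc[k * 4 + p] = fe[p];
          inh[k * 4 + p] = fi[p];
          ext[k * 4 + p] = fx[p];
          inp[k * 4 + p] = fu[p];
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cmc_integrate_cpp")]]
List cmc_integrate_cpp(NumericVector kappa, NumericMatrix gintr,
                       NumericMatrix Af, NumericMatrix Ab, NumericVector Cvec,
                       double onset, double dispersion, int n_out,
                       double dt_out, int substeps) {
  const int R = gintr.ncol();
  CMCSys sys{R, kappa.begin(), gintr.begin(), Af.begin(), Ab.begin(),
             Cvec.begin(), onset, dispersion};
  const int ns = 8 * R, np = 4 * R;
  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), xt(ns);
  NumericMatrix V(n_out + 1, np), EXC(n_out + 1, np), INH(n_out + 1, np),
      EXT(n_out + 1, np), INP(n_out + 1, np);
  std::vector<double> ce(np), ci(np), cx(np), cu(np);
  const double h = dt_out / substeps;
  bool ok = true;
  for (int i = 0; i <= n_out; ++i) {
    const double t0 = i * dt_out;
    // record state and afferent components at the output sample
    sys.deriv(t0, x.data(), k1.data(), ce.data(), ci.data(), cx.data(),
              cu.data());
    for (int j = 0; j < np; ++j) {
      const int k = j / 4, p = j % 4;
      V(i, j) = x[k * 8 + p];
      EXC(i, j) = ce[j];
      INH(i, j) = ci[j];
      EXT(i, j) = cx[j];
      INP(i, j) = cu[j];
      if (!std::isfinite(x[k * 8 + p])) ok = false;
    }
    if (!ok || i == n_out) break;
    for (int ss = 0; ss < substeps; ++ss) {
      const double t = t0 + ss * h;
      sys.deriv(t, x.data(), k1.data());
      for (int j = 0; j < ns; ++j) xt[j] = x[j] + 0.5 * h * k1[j];
      sys.deriv(t + 0.5 * h, xt.data(), k2.data());
      for (int j = 0; j < ns; ++j) xt[j] = x[j] + 0.5 * h * k2[j];
      sys.deriv(t + 0.5 * h, xt.data(), k3.data());
      for (int j = 0; j < ns; ++j) xt[j] = x[j] + h * k3[j];
      sys.deriv(t + h, xt.data(), k4.data());
      for (int j = 0; j < ns; ++j)
        x[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
  }
  return List::create(_["V"] = V, _["exc"] = EXC, _["inh"] = INH,
                      _["ext"] = EXT, _["inp"] = INP, _["finite"] = ok);
}

namespace {

// Balloon model in log-states for (inflow, volume, dHb) so positivity is
// structural.  State: (hs, ln hin, ln hv, ln hq); rest is (0, 0, 0, 0).
inline void balloon_deriv(const double* x, double z, double eta, double chi,
                          double tauh, double alpha, double E0, double* dx) {
  const double hs = x[0];
  const double hin = std::exp(x[1]);
  const double hv = std::exp(x[2]);
  const double hq = std::exp(x[3]);
  const double fout = std::pow(hv, 1.0 / alpha);
  const double extr = hin * (1.0 - std::pow(1.0 - E0, 1.0 / hin)) / E0;
  dx[0] = z - eta * hs - chi * (hin - 1.0);
  dx[1] = hs / hin;
  dx[2] = (hin - fout) / (tauh * hv);
  dx[3] = (extr - fout * hq / hv) / (tauh * hq);
}

}  // namespace

// [[Rcpp::export(name = ".balloon_integrate_cpp")]]
List balloon_integrate_cpp(NumericMatrix z, double dt, NumericVector eta,
                           NumericVector chi, NumericVector tauh,
                           NumericVector alpha, NumericVector E0,
                           NumericVector eps, double V0) {
  const int n = z.nrow(), R = z.ncol();
  NumericMatrix y(n, R), HV(n, R), HQ(n, R);
  bool ok = true;
  for (int r = 0; r < R; ++r) {
    const double k1c = 6.9 * E0[r];
    const double k2c = eps[r] * E0[r];
    const double k3c = 1.0 - eps[r];
    double x[4] = {0.0, 0.0, 0.0, 0.0};
    double a[4], b[4], c[4], d[4], xt[4];
    for (int i = 0; i < n; ++i) {
      const double hv = std::exp(x[2]), hq = std::exp(x[3]);
      HV(i, r) = hv;
      HQ(i, r) = hq;
      y(i, r) = V0 * (k1c * (1.0 - hq) + k2c * (1.0 - hq / hv) +
                      k3c * (1.0 - hv));
      if (!std::isfinite(y(i, r))) ok = false;
      if (!ok || i == n - 1) break;
      const double z0 = z(i, r), z1 = z(i + 1, r), zm = 0.5 * (z0 + z1);
      balloon_deriv(x, z0, eta[r], chi[r], tauh[r], alpha[r], E0[r], a);
      for (int j = 0; j < 4; ++j) xt[j] = x[j] + 0.5 * dt * a[j];
      balloon_deriv(xt, zm, eta[r], chi[r], tauh[r], alpha[r], E0[r], b);
      for (int j = 0; j < 4; ++j) xt[j] = x[j] + 0.5 * dt * b[j];
      balloon_deriv(xt, zm, eta[r], chi[r], tauh[r], alpha[r], E0[r], c);
      for (int j = 0; j < 4; ++j) xt[j] = x[j] + dt * c[j];
      balloon_deriv(xt, z1, eta[r], chi[r], tauh[r], alpha[r], E0[r], d);
      for (int j = 0; j < 4; ++j)
        x[j] += dt / 6.0 * (a[j] + 2.0 * b[j] + 2.0 * c[j] + d[j]);
    }
    if (!ok) break;
  }
  return List::create(_["y"] = y, _["hv"] = HV, _["hq"] = HQ,
                      _["finite"] = ok);
}
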