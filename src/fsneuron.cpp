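// Compiled core of the FS interneuron model: vector field and fixed-step RK4.
// Mirrors the pure-R reference implementation in R/model.R; units mV, ms,
// pA, nS, pF, uM.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rate {
  int type;        // 0 linoid, 1 exponential, 2 sigmoid, 3 constant
  double C, Vh, s;
};

inline double rate_eval(const Rate &r, double V) {
  switch (r.type) {
  case 0: {
    double u = (V - r.Vh) / r.s;
    if (std::fabs(u) < 1e-7)  // analytic limit C*s at the removable pole
      return r.C * r.s * (1.0 - 0.5 * u);
    return r.C * (V - r.Vh) / (std::exp(u) - 1.0);
  }
  case 1:
    return r.C * std::exp((V - r.Vh) / r.s);
  case 2:
    return r.C / (1.0 + std::exp(-(V - r.Vh) / r.s));
  default:
    return r.C;
  }
}

// parameter vector layout (see .pack_params in R/simulate.R)
enum {
  P_CM, P_GNA, P_GKV1, P_GKV3, P_GSK, P_GCA, P_GLEAK,
  P_VNA, P_VK, P_VCA, P_VLEAK,
  P_KONSK, P_KOFFSK, P_GAMMA, P_D, P_A, P_CAREST, P_MGI, P_F,
  P_LITERALTAUK, P_SKEXP, P_NPAR
};

struct Model {
  double p[P_NPAR];
  Rate rates[8];  // m.a, m.b, h.a, h.b, n1.a, n1.b, n3.a, n3.b
  int scheme;     // 0 none, 1 pv, 2 slow, 3 fast
  double sp[5];   // pv: BT, kon_ca, koff_ca, kon_mg, koff_mg
                  // slow/fast: BT, kon, koff
  double phi;     // uM/ms per pA of inward Ca current
  int ns;

  void init() {
    phi = 1e6 / (2.0 * p[P_F] * p[P_A] * p[P_D]);
    ns = 6 + (scheme == 1 ? 2 : (scheme >= 2 ? 1 : 0));
  }

  // y: V h n1 n3 k Ca [PVCa PVMg | BCa]
  void rhs(const double *y, double iapp, double *dy) const {
    const double V = y[0], h = y[1], n1 = y[2], n3 = y[3], k = y[4],
                 Ca = y[5];
    const double am = rate_eval(rates[0], V), bm = rate_eval(rates[1], V);
    const double ah = rate_eval(rates[2], V), bh = rate_eval(rates[3], V);
    const double an1 = rate_eval(rates[4], V), bn1 = rate_eval(rates[5], V);
    const double an3 = rate_eval(rates[6], V), bn3 = rate_eval(rates[7], V);
    const double minf = am / (am + bm);
    const double ainf = 1.0 / (1.0 + std::exp((-6.0 - V) / 7.775));

    const double INa = p[P_GNA] * minf * minf * minf * h * (V - p[P_VNA]);
    const double IKv1 = p[P_GKV1] * n1 * n1 * n1 * n1 * (V - p[P_VK]);
    const double IKv3 = p[P_GKV3] * n3 * n3 * (V - p[P_VK]);
    const double ISK =
        p[P_GSK] * std::pow(k, p[P_SKEXP]) * (V - p[P_VK]);
    const double ICa = p[P_GCA] * ainf * ainf * (V - p[P_VCA]);
    const double Ileak = p[P_GLEAK] * (V - p[P_VLEAK]);

    dy[0] = (-(INa + IKv1 + IKv3 + ISK + ICa + Ileak) + iapp) / p[P_CM];
    dy[1] = ah * (1.0 - h) - bh * h;
    dy[2] = an1 * (1.0 - n1) - bn1 * n1;
    dy[3] = an3 * (1.0 - n3) - bn3 * n3;

    const double KSK = p[P_KOFFSK] / p[P_KONSK];
    const double kinf = Ca / (KSK + Ca);
    const double tauk = p[P_LITERALTAUK] > 0.5
                            ? 1.0 / (KSK + Ca)
                            : 1.0 / (p[P_KONSK] * Ca + p[P_KOFFSK]);
    dy[4] = (kinf - k) / tauk;

    double dCa = -ICa * phi - p[P_GAMMA] * (Ca - p[P_CAREST]);
    if (scheme == 1) {
      const double PVCa = y[6], PVMg = y[7];
      const double free = sp[0] - PVCa - PVMg;
      const double dPVCa = sp[1] * Ca * free - sp[2] * PVCa;
      const double dPVMg = sp[3] * p[P_MGI] * free - sp[4] * PVMg;
      dy[6] = dPVCa;
      dy[7] = dPVMg;
      dCa -= dPVCa;
    } else if (scheme >= 2) {
      const double BCa = y[6];
      const double dBCa = sp[1] * Ca * (sp[0] - BCa) - sp[2] * BCa;
      dy[6] = dBCa;
      dCa -= dBCa;
    }
    dy[5] = dCa;
  }

  void currents(const double *y, double *I) const {
    const double V = y[0];
    const double am = rate_eval(rates[0], V), bm = rate_eval(rates[1], V);
    const double minf = am / (am + bm);
    const double ainf = 1.0 / (1.0 + std::exp((-6.0 - V) / 7.775));
    I[0] = p[P_GNA] * minf * minf * minf * y[1] * (V - p[P_VNA]);
    I[1] = p[P_GKV1] * y[2] * y[2] * y[2] * y[2] * (V - p[P_VK]);
    I[2] = p[P_GKV3] * y[3] * y[3] * (V - p[P_VK]);
    I[3] = p[P_GSK] * std::pow(y[4], p[P_SKEXP]) * (V - p[P_VK]);
    I[4] = p[P_GCA] * ainf * ainf * (V - p[P_VCA]);
    I[5] = p[P_GLEAK] * (V - p[P_VLEAK]);
  }
};

Model build_model(const NumericVector &pars, const NumericMatrix &ratemat,
                  int scheme, const NumericVector &scheme_pars) {
  Model m;
  if (pars.size() != P_NPAR) stop("parameter vector has wrong length");
  for (int i = 0; i < P_NPAR; ++i) m.p[i] = pars[i];
  if (ratemat.nrow() != 8 || ratemat.ncol() != 4)
    stop("rate matrix must be 8 x 4");
  for (int i = 0; i < 8; ++i) {
    m.rates[i].type = (int)ratemat(i, 0);
    m.rates[i].C = ratemat(i, 1);
    m.rates[i].Vh = ratemat(i, 2);
    m.rates[i].s = ratemat(i, 3);
  }
  m.scheme = scheme;
  for (int i = 0; i < 5; ++i)
    m.sp[i] = i < scheme_pars.size() ? scheme_pars[i] : 0.0;
  m.init();
  return m;
}

inline double stim_at(const NumericMatrix &S, double t) {
  for (int i = 0; i < S.nrow(); ++i) {
    const double t0 = S(i, 0), t1 = S(i, 1);
    // small tolerance so accumulated floating-point drift in the substep
    // times never drops the final segment edge
    const bool inside = (i == S.nrow() - 1) ? (t >= t0 && t <= t1 + 1e-9)
                                            : (t >= t0 && t < t1);
    if (inside) {
      if (S(i, 4) > 0.5)  // ramp
        return S(i, 2) + (S(i, 3) - S(i, 2)) * (t - t0) / (t1 - t0);
      return S(i, 2);
    }
  }
  return 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(NumericVector y, double iapp, NumericVector pars,
                      NumericMatrix ratemat, int scheme,
                      NumericVector scheme_pars) {
  Model m = build_model(pars, ratemat, scheme, scheme_pars);
  if (y.size() != m.ns) stop("state vector has wrong length");
  NumericVector dy(m.ns);
  m.rhs(y.begin(), iapp, dy.begin());
  return dy;
}

// [[Rcpp::export(name = ".cpp_currents")]]
NumericVector cpp_currents(NumericVector y, NumericVector pars,
                           NumericMatrix ratemat) {
  Model m = build_model(pars, ratemat, 0, NumericVector(0));
  NumericVector I(6);
  m.currents(y.begin(), I.begin());
  return I;
}

// Classic fixed-step RK4 over n_steps of size dt starting at t0; state and
// currents recorded every `stride` steps (step 0 included).
// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(NumericVector y0, double t0, double dt, int n_steps,
                   int stride, NumericVector pars, NumericMatrix ratemat,
                   int scheme, NumericVector scheme_pars,
                   NumericMatrix stim) {
  Model m = build_model(pars, ratemat, scheme, scheme_pars);
  const int ns = m.ns;
  if (y0.size() != ns) stop("initial state has wrong length");
  if (dt <= 0) stop("dt must be > 0");
  if (stride < 1) stop("record stride must be >= 1");

  const int n_rec = n_steps / stride + 1;
  NumericVector time(n_rec);
  NumericMatrix Y(n_rec, ns), I(n_rec, 6);
  NumericVector iapp_rec(n_rec);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns), Ibuf(6);

  int irec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = t0 + step * dt;
    if (step % stride == 0 && irec < n_rec) {
      if (!std::isfinite(y[0]))
        stop("non-finite state at t = %g ms (integration unstable; reduce dt)",
             t);
      time[irec] = t;
      for (int j = 0; j < ns; ++j) Y(irec, j) = y[j];
      m.currents(y.data(), Ibuf.data());
      for (int j = 0; j < 6; ++j) I(irec, j) = Ibuf[j];
      iapp_rec[irec] = stim_at(stim, t);
      ++irec;
    }
    if (step == n_steps) break;

    const double i1 = stim_at(stim, t);
    const double i2 = stim_at(stim, t + 0.5 * dt);
    const double i4 = stim_at(stim, t + dt);
    m.rhs(y.data(), i1, k1.data());
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    m.rhs(tmp.data(), i2, k2.data());
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    m.rhs(tmp.data(), i2, k3.data());
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + dt * k3[j];
    m.rhs(tmp.data(), i4, k4.data());
    for (int j = 0; j < ns; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }

  return List::create(_["time"] = time, _["state"] = Y, _["currents"] = I,
                      _["iapp"] = iapp_rec);
}
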