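// Compartmental motoneuron integrator: soma + four dendritic compartments.
//
// Soma carries the spike conductances (Na, delayed-rectifier K), the
// medium-AHP Ca-activated K conductance driven by a per-spike calcium
// increment with first-order removal, and an HCN conductance.  Each
// dendritic compartment carries the slowly activating L-type Ca persistent
// inward current (PIC), an HCN conductance, and the synaptic conductances.
// Integration is exponential Euler on voltages and gates; voltage-dependent
// rate functions are tabulated once per call (0.05 mV grid) so the grid
// sweeps stay cheap.
//
// Units: mV, ms, uS, nF, nA.  Command traces are zero-order-held at their
// own sampling interval dt_cmd.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int NCOMP = 5;    // soma + 4 dendrites
const int NDEND = 4;
const int NSTATE = 18;  // V[5], mNa, hNa, nK, Ca, mCaL[4], hHCN[5]

// Traub/RTM-style spike kinetics.  Singular points handled by l'Hopital.
inline double ratefun(double v, double a, double b, double c) {
  // a*(v+b)/(1-exp(-(v+b)/c)); limit a*c at v = -b
  double x = v + b;
  if (std::fabs(x) < 1e-6) return a * c;
  return a * x / (1.0 - std::exp(-x / c));
}
inline double alpha_m(double v) { return ratefun(v, 0.32, 54.0, 4.0); }
inline double beta_m(double v) {
  double x = v + 27.0;
  if (std::fabs(x) < 1e-6) return 0.28 * 5.0;
  return 0.28 * x / (std::exp(x / 5.0) - 1.0);
}
inline double alpha_h(double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); }
inline double beta_h(double v) { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); }
inline double alpha_n(double v) { return ratefun(v, 0.032, 52.0, 5.0); }
inline double beta_n(double v) { return 0.5 * std::exp(-(v + 57.0) / 40.0); }

struct Tables {
  // voltage grid
  double v0, dv;
  int n;
  std::vector<double> minf, mdec, hinf, hdec, ninf, ndec, qinf;
  // PIC activation on shifted axis x = V - Vhalf
  double x0, dx;
  int nx;
  std::vector<double> picinf;

  void build(double dt, double kCaL, double tauHCN, double vHCNhalf,
             double kHCN) {
    v0 = -130.0; dv = 0.05; n = (int)((80.0 - v0) / dv) + 1;
    minf.resize(n); mdec.resize(n); hinf.resize(n); hdec.resize(n);
    ninf.resize(n); ndec.resize(n); qinf.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = v0 + i * dv;
      double am = alpha_m(v), bm = beta_m(v);
      double ah = alpha_h(v), bh = beta_h(v);
      double an = alpha_n(v), bn = beta_n(v);
      minf[i] = am / (am + bm); mdec[i] = std::exp(-dt * (am + bm));
      hinf[i] = ah / (ah + bh); hdec[i] = std::exp(-dt * (ah + bh));
      ninf[i] = an / (an + bn); ndec[i] = std::exp(-dt * (an + bn));
      qinf[i] = 1.0 / (1.0 + std::exp((v - vHCNhalf) / kHCN));
    }
    x0 = -90.0; dx = 0.05; nx = (int)((90.0 - x0) / dx) + 1;
    picinf.resize(nx);
    for (int i = 0; i < nx; ++i) {
      double x = x0 + i * dx;
      picinf[i] = 1.0 / (1.0 + std::exp(-x / kCaL));
    }
  }
  inline int vidx(double v) const {
    int i = (int)((v - v0) / dv + 0.5);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
  inline double pic(double x) const {
    int i = (int)((x - x0) / dx + 0.5);
    if (i < 0) i = 0;
    if (i >= nx) i = nx - 1;
    return picinf[i];
  }
};

// per-neuron parameter columns of the matrix handed in from R
enum {
  P_CSOMA, P_CDEND, P_GLSOMA, P_GLDEND, P_GC,
  P_GNA, P_GK, P_GAHP, P_DCA, P_TAUCA,
  P_GCAL, P_VHALF, P_GHCNS, P_GHCND, P_WEIGHT,
  P_VSHIFT, P_SYNSCALE, P_NPAR
};

// global parameter entries
enum {
  G_EL, G_ENA, G_EK, G_EEXC, G_EINH, G_EHCN, G_ECAL,
  G_KCAL, G_TAUCAL, G_VSPIKE, G_REFRAC, G_KCA,
  G_TAUHCN, G_VHCNHALF, G_KHCN, G_NPAR
};

}  // namespace

// [[Rcpp::export(name = ".simulate_pool_cpp")]]
List simulate_pool_cpp(NumericMatrix P, NumericVector glob, double Rmod,
                       NumericVector gexc_cmd, NumericVector ginh_cmd,
                       double dt, double dt_cmd, double T_ms,
                       int record_every, bool record_v,
                       Nullable<NumericMatrix> state0_ = R_NilValue) {
  const int nn = P.nrow();
  if (P.ncol() != P_NPAR) stop("parameter matrix has wrong column count");
  if (glob.size() != G_NPAR) stop("global parameter vector has wrong length");
  if (dt <= 0 || dt > 0.1 + 1e-12) stop("dt must be in (0, 0.1] ms");

  const double EL = glob[G_EL], ENa = glob[G_ENA], EK = glob[G_EK];
  const double Eexc = glob[G_EEXC], Einh = glob[G_EINH], EHCN = glob[G_EHCN];
  const double ECaL = glob[G_ECAL], kCaL = glob[G_KCAL];
  const double tauCaL = glob[G_TAUCAL];
  const double Vspike = glob[G_VSPIKE], refrac = glob[G_REFRAC];
  const double KCa = glob[G_KCA], tauHCN = glob[G_TAUHCN];

  Tables tab;
  tab.build(dt, kCaL, tauHCN, glob[G_VHCNHALF], glob[G_KHCN]);
  const double pic_dec = std::exp(-dt / tauCaL);
  const double hcn_dec = std::exp(-dt / tauHCN);

  const int nsteps = (int)std::lround(T_ms / dt);
  const int ncmd = gexc_cmd.size();
  if (ginh_cmd.size() != ncmd) stop("command traces must have equal length");

  NumericMatrix state_out(nn, NSTATE);
  bool have_state0 = state0_.isNotNull();
  NumericMatrix state0;
  if (have_state0) {
    state0 = NumericMatrix(state0_);
    if (state0.nrow() != nn || state0.ncol() != NSTATE)
      stop("initial state matrix has wrong dimensions");
  }

  List spikes(nn);
  List vtraces(nn);
  const int nrec = record_v ? (nsteps / record_every + 1) : 0;

  for (int in = 0; in < nn; ++in) {
    const double Cs = P(in, P_CSOMA), Cd = P(in, P_CDEND);
    const double gLs = P(in, P_GLSOMA), gLd = P(in, P_GLDEND);
    const double gc = P(in, P_GC);
    const double gNa = P(in, P_GNA), gK = P(in, P_GK);
    const double gAHP = P(in, P_GAHP), dCa = P(in, P_DCA);
    const double tauCa = P(in, P_TAUCA);
    const double gCaL = Rmod * P(in, P_GCAL);
    const double Vhalf = P(in, P_VHALF);
    const double gHs = P(in, P_GHCNS), gHd = P(in, P_GHCND);
    const double w = P(in, P_WEIGHT);
    const double vshift = P(in, P_VSHIFT);   // spike-threshold shift, mV
    const double syn = P(in, P_SYNSCALE);    // density -> absolute scaling
    const double ca_dec = std::exp(-dt / tauCa);

    double V[NCOMP], mCaL[NDEND], hH[NCOMP];
    double mNa, hNa, nK, Ca;
    if (have_state0) {
      for (int j = 0; j < NCOMP; ++j) V[j] = state0(in, j);
      mNa = state0(in, 5); hNa = state0(in, 6); nK = state0(in, 7);
      Ca = state0(in, 8);
      for (int j = 0; j < NDEND; ++j) mCaL[j] = state0(in, 9 + j);
      for (int j = 0; j < NCOMP; ++j) hH[j] = state0(in, 13 + j);
    } else {
      for (int j = 0; j < NCOMP; ++j) V[j] = EL;
      int ivs = tab.vidx(EL - vshift);
      int iv = tab.vidx(EL);
      mNa = tab.minf[ivs]; hNa = tab.hinf[ivs]; nK = tab.ninf[ivs];
      Ca = 0.0;
      for (int j = 0; j < NDEND; ++j) mCaL[j] = tab.pic(EL - Vhalf);
      for (int j = 0; j < NCOMP; ++j) hH[j] = tab.qinf[iv];
    }

    std::vector<double> sp;
    sp.reserve(512);
    NumericMatrix vrec;
    if (record_v) vrec = NumericMatrix(2, nrec);  // soma + first dendrite
    int irec = 0;
    double tlast = -1e9;
    bool above = V[0] >= Vspike;

    for (int k = 0; k < nsteps; ++k) {
      const double t = k * dt;
      int ic = (int)(t / dt_cmd);
      if (ic >= ncmd) ic = ncmd - 1;
      // command traces are densities; absolute conductance scales with the
      // neuron's membrane area factor, split over the 4 dendrites
      const double ge = w * syn * gexc_cmd[ic] * 0.25;
      const double gi = syn * ginh_cmd[ic] * 0.25;

      if (record_v && (k % record_every == 0) && irec < nrec) {
        vrec(0, irec) = V[0];
        vrec(1, irec) = V[1];
        ++irec;
      }

      // --- soma ---
      // spike kinetics are evaluated at a shifted voltage: the per-neuron
      // excitability gradient of the pool
      const int iv0 = tab.vidx(V[0] - vshift);
      const double m3h = mNa * mNa * mNa * hNa;
      const double n4 = nK * nK * nK * nK;
      const double aAHP = Ca / (Ca + KCa);
      double dendsum = V[1] + V[2] + V[3] + V[4];
      double G = gLs + gNa * m3h + gK * n4 + gAHP * aAHP + gHs * hH[0] +
                 4.0 * gc;
      double Num = gLs * EL + gNa * m3h * ENa + (gK * n4 + gAHP * aAHP) * EK +
                   gHs * hH[0] * EHCN + gc * dendsum;
      double Vinf = Num / G;
      const double V0new = Vinf + (V[0] - Vinf) * std::exp(-dt * G / Cs);

      // soma gates (exponential Euler at current voltage)
      mNa = tab.minf[iv0] + (mNa - tab.minf[iv0]) * tab.mdec[iv0];
      hNa = tab.hinf[iv0] + (hNa - tab.hinf[iv0]) * tab.hdec[iv0];
      nK = tab.ninf[iv0] + (nK - tab.ninf[iv0]) * tab.ndec[iv0];
      const int iv0u = tab.vidx(V[0]);  // HCN is not part of the gradient
      hH[0] = tab.qinf[iv0u] + (hH[0] - tab.qinf[iv0u]) * hcn_dec;
      Ca *= ca_dec;

      // --- dendrites ---
      double Vnew[NDEND];
      for (int j = 0; j < NDEND; ++j) {
        const double Vd = V[1 + j];
        const int ivd = tab.vidx(Vd);
        const double gp = gCaL * mCaL[j];
        double Gd = gLd + gp + gHd * hH[1 + j] + ge + gi + gc;
        double Nd = gLd * EL + gp * ECaL + gHd * hH[1 + j] * EHCN +
                    ge * Eexc + gi * Einh + gc * V[0];
        double Vdinf = Nd / Gd;
        Vnew[j] = Vdinf + (Vd - Vdinf) * std::exp(-dt * Gd / Cd);
        const double pinf = tab.pic(Vd - Vhalf);
        mCaL[j] = pinf + (mCaL[j] - pinf) * pic_dec;
        hH[1 + j] = tab.qinf[ivd] + (hH[1 + j] - tab.qinf[ivd]) * hcn_dec;
      }

      // spike detection: upward crossing with absolute refractory lockout
      if (!above && V0new >= Vspike && (t - tlast) >= refrac) {
        sp.push_back(t + dt);
        tlast = t + dt;
        Ca += dCa;
      }
      above = V0new >= Vspike;

      V[0] = V0new;
      for (int j = 0; j < NDEND; ++j) V[1 + j] = Vnew[j];

      if ((k & 1023) == 0) {
        for (int j = 0; j < NCOMP; ++j) {
          if (!std::isfinite(V[j]))
            stop("integration failure: non-finite voltage in neuron %d, "
                 "compartment %d at t = %.3f ms", in + 1, j, t);
        }
      }
    }

    state_out(in, 0) = V[0];
    for (int j = 0; j < NDEND; ++j) state_out(in, 1 + j) = V[1 + j];
    state_out(in, 5) = mNa; state_out(in, 6) = hNa; state_out(in, 7) = nK;
    state_out(in, 8) = Ca;
    for (int j = 0; j < NDEND; ++j) state_out(in, 9 + j) = mCaL[j];
    for (int j = 0; j < NCOMP; ++j) state_out(in, 13 + j) = hH[j];

    spikes[in] = NumericVector(sp.begin(), sp.end());
    if (record_v) vtraces[in] = vrec;
  }

  return List::create(_["spikes"] = spikes,
                      _["v"] = record_v ? (SEXP)vtraces : R_NilValue,
                      _["state"] = state_out);
}
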