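// Core integrator for the discrete monodomain model:
//   C_m dV_i/dt = sum_nb eta g_gap (V_nb - V_i) - I_ion(V_i, ...)
// with the ten Tusscher-Panfilov 2006 (TP06) human ventricular myocyte
// as the reaction term.  Voltage and concentrations advance by forward
// Euler; Hodgkin-Huxley gates advance by Rush-Larsen exponential updates
// (the m-gate time constant drops to ~1 us at depolarized potentials, far
// below any usable dt, so a plain Euler gate update is unconditionally
// unstable at dt = 0.02 ms).
//
// All voltage-dependent rate and current factors are pre-tabulated on a
// fine V grid and linearly interpolated, so the inner loop is free of
// exp/log calls.  Reversal potentials are refreshed on a configurable
// stride (concentrations drift on a much slower time scale than dt).

#pragma GCC optimize("O3")
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdlib>
using namespace Rcpp;

namespace {

struct P {
  double RR, TT, FF, Cap, Vc, Vsr, Vss;
  double Ko, Nao, Cao, pKNa;
  double GNa, GK1, Gto, GKr, GKs, GCaL, GbNa, GbCa, GpCa, GpK;
  double PNaK, KmK, KmNa, knaca, KmNai, KmCa, ksat, ngamma;
  double KpCa, Vmaxup, Kup, Vrel, Vleak, Vxfer;
  double k1p, k2p, k3, k4, maxsr, minsr, EC;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  double tauf_scale, taus_scale, tauhj_rec_scale;
};

double need(const NumericVector& pv, const char* nm) {
  if (!pv.containsElementNamed(nm))
    stop("parameter vector is missing '%s'", std::string(nm));
  return as<double>(pv[nm]);
}

P unpack(const NumericVector& pv) {
  P p;
  p.RR = need(pv, "Rgas");   p.TT = need(pv, "Temp");  p.FF = need(pv, "Faraday");
  p.Cap = need(pv, "Cap");   p.Vc = need(pv, "Vc");    p.Vsr = need(pv, "Vsr");
  p.Vss = need(pv, "Vss");
  p.Ko = need(pv, "Ko");     p.Nao = need(pv, "Nao");  p.Cao = need(pv, "Cao");
  p.pKNa = need(pv, "pKNa");
  p.GNa = need(pv, "GNa");   p.GK1 = need(pv, "GK1");  p.Gto = need(pv, "Gto");
  p.GKr = need(pv, "GKr");   p.GKs = need(pv, "GKs");  p.GCaL = need(pv, "GCaL");
  p.GbNa = need(pv, "GbNa"); p.GbCa = need(pv, "GbCa");
  p.GpCa = need(pv, "GpCa"); p.GpK = need(pv, "GpK");
  p.PNaK = need(pv, "PNaK"); p.KmK = need(pv, "KmK");  p.KmNa = need(pv, "KmNa");
  p.knaca = need(pv, "kNaCa"); p.KmNai = need(pv, "KmNai");
  p.KmCa = need(pv, "KmCa"); p.ksat = need(pv, "ksat"); p.ngamma = need(pv, "gamma");
  p.KpCa = need(pv, "KpCa"); p.Vmaxup = need(pv, "Vmaxup"); p.Kup = need(pv, "Kup");
  p.Vrel = need(pv, "Vrel"); p.Vleak = need(pv, "Vleak");   p.Vxfer = need(pv, "Vxfer");
  p.k1p = need(pv, "k1p");   p.k2p = need(pv, "k2p");  p.k3 = need(pv, "k3");
  p.k4 = need(pv, "k4");     p.maxsr = need(pv, "maxsr"); p.minsr = need(pv, "minsr");
  p.EC = need(pv, "EC");
  p.Bufc = need(pv, "Bufc"); p.Kbufc = need(pv, "Kbufc");
  p.Bufsr = need(pv, "Bufsr"); p.Kbufsr = need(pv, "Kbufsr");
  p.Bufss = need(pv, "Bufss"); p.Kbufss = need(pv, "Kbufss");
  p.tauf_scale = pv.containsElementNamed("tauf_scale") ? as<double>(pv["tauf_scale"]) : 1.0;
  p.taus_scale = pv.containsElementNamed("taus_scale") ? as<double>(pv["taus_scale"]) : 1.0;
  p.tauhj_rec_scale = pv.containsElementNamed("tauhj_rec_scale") ?
      as<double>(pv["tauhj_rec_scale"]) : 1.0;
  return p;
}

// ---- Voltage-dependent gate rates and current factors (TP06, epicardial s/r) ----

struct Rates {
  double inf[11], tau[11];  // m h j xr1 xr2 xs r s d f f2
};

void gate_rates(double V, const P& p, Rates& g) {
  // INa gates
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  g.inf[0] = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  g.tau[0] = am * bm;
  g.inf[1] = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g.tau[1] = 1.0 / (ah + bh);
  g.inf[2] = g.inf[1];
  g.tau[2] = 1.0 / (aj + bj);
  // restitution variant: accelerated recovery from I_Na inactivation
  // below -40 mV (post-repolarization refractoriness knob); the
  // depolarized (inactivation) branch is untouched
  if (V < -40.0) {
    g.tau[1] *= p.tauhj_rec_scale;
    g.tau[2] *= p.tauhj_rec_scale;
  }
  // IKr
  g.inf[3] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double ax1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bx1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  g.tau[3] = ax1 * bx1;
  g.inf[4] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double ax2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bx2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  g.tau[4] = ax2 * bx2;
  // IKs
  g.inf[5] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  g.tau[5] = axs * bxs + 80.0;
  // Ito (epicardial r and s)
  g.inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  g.tau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  g.inf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  g.tau[7] = p.taus_scale *
             (85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0);
  // ICaL gates
  g.inf[8] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  g.tau[8] = ad * bd + cd;
  g.inf[9] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  g.tau[9] = p.tauf_scale *
             (1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
              200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
              180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0);
  g.inf[10] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  g.tau[10] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
              31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
              80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
}

// Lookup-table bundle.  vtab has NCOL entries per V sample, row-major by
// V index, so one interpolation touches two contiguous rows.
struct Tables {
  double vmin, inv_dv;
  int n;
  std::vector<double> tab;       // n x NCOL
  static const int NCOL = 28;
  double kmin, inv_dk;           // IK1 rectifier vs (V - EK)
  int nk;
  std::vector<double> k1tab;
};

enum {
  C_MINF, C_MRL, C_HINF, C_HRL, C_JINF, C_JRL,
  C_X1INF, C_X1RL, C_X2INF, C_X2RL, C_XSINF, C_XSRL,
  C_RINF, C_RRL, C_SINF, C_SRL, C_DINF, C_DRL,
  C_FINF, C_FRL, C_F2INF, C_F2RL,
  C_PCAL, C_QCAL, C_ANACA, C_BNACA, C_FNAK, C_IPK
};

Tables build_tables(const P& p, double dt) {
  Tables T;
  T.vmin = -110.0; T.n = 4001; T.inv_dv = (T.n - 1) / (90.0 - T.vmin);
  double dv = 1.0 / T.inv_dv;
  T.tab.assign((size_t)T.n * Tables::NCOL, 0.0);
  double rtf = p.RR * p.TT / p.FF;
  for (int i = 0; i < T.n; ++i) {
    double V = T.vmin + i * dv;
    Rates g;
    gate_rates(V, p, g);
    double* row = &T.tab[(size_t)i * Tables::NCOL];
    for (int k = 0; k < 11; ++k) {
      row[2 * k] = g.inf[k];
      row[2 * k + 1] = std::exp(-dt / g.tau[k]);
    }
    // ICaL driving-force split: ICaL = d f f2 fcass (PCAL * CaSS - QCAL)
    double x = 2.0 * (V - 15.0) * p.FF / (p.RR * p.TT);
    double common = p.GCaL * 4.0 * (V - 15.0) * p.FF * p.FF / (p.RR * p.TT);
    double pc, qc;
    if (std::fabs(x) < 1e-7) {       // limit (V -> 15 mV)
      double lim = p.GCaL * 2.0 * p.FF;  // common / x as x -> 0
      pc = lim * 0.25; qc = lim * p.Cao;
    } else {
      double em1 = std::expm1(x);
      pc = common * 0.25 * std::exp(x) / em1;
      qc = common * p.Cao / em1;
    }
    row[C_PCAL] = pc; row[C_QCAL] = qc;
    // INaCa split: INaCa = ANACA * Nai^3 - BNACA * Cai
    double den = (p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao) *
                 (p.KmCa + p.Cao) *
                 (1.0 + p.ksat * std::exp((p.ngamma - 1.0) * V / rtf));
    row[C_ANACA] = p.knaca * std::exp(p.ngamma * V / rtf) * p.Cao / den;
    row[C_BNACA] = p.knaca * std::exp((p.ngamma - 1.0) * V / rtf) *
                   p.Nao * p.Nao * p.Nao * 2.5 / den;
    // INaK voltage factor (Nai part applied per node)
    row[C_FNAK] = p.PNaK * (p.Ko / (p.Ko + p.KmK)) /
                  (1.0 + 0.1245 * std::exp(-0.1 * V / rtf) +
                   0.0353 * std::exp(-V / rtf));
    row[C_IPK] = p.GpK / (1.0 + std::exp((25.0 - V) / 5.98));
  }
  // IK1 inward rectifier vs x = V - EK (GK1 folded in)
  T.kmin = -150.0; T.nk = 8001; T.inv_dk = (T.nk - 1) / (250.0 - T.kmin);
  double dk = 1.0 / T.inv_dk;
  T.k1tab.resize(T.nk);
  for (int i = 0; i < T.nk; ++i) {
    double x = T.kmin + i * dk;
    double a = 0.1 / (1.0 + std::exp(0.06 * (x - 200.0)));
    double b = (3.0 * std::exp(0.0002 * (x + 100.0)) + std::exp(0.1 * (x - 10.0))) /
               (1.0 + std::exp(-0.5 * x));
    T.k1tab[i] = p.GK1 * a / (a + b);
  }
  return T;
}

inline void vlookup(const Tables& T, double V, const double*& r0, const double*& r1,
                    double& w1) {
  double u = (V - T.vmin) * T.inv_dv;
  if (u < 0.0) u = 0.0;
  if (u > T.n - 1.001) u = T.n - 1.001;
  int j = (int)u;
  w1 = u - j;
  r0 = &T.tab[(size_t)j * Tables::NCOL];
  r1 = r0 + Tables::NCOL;
}

inline double k1lookup(const Tables& T, double x) {
  double u = (x - T.kmin) * T.inv_dk;
  if (u < 0.0) u = 0.0;
  if (u > T.nk - 1.001) u = T.nk - 1.001;
  int j = (int)u;
  double w = u - j;
  return T.k1tab[j] * (1.0 - w) + T.k1tab[j + 1] * w;
}

}  // namespace


// One forward step over all myocyte nodes.  Cloned per ISA level so the
// package runs (and is merely slower) on CPUs without AVX2.
struct StepConsts {
  double dt, ccoup, act_threshold;
  double Gto, GpCa, KmNa, KpCa, sqrtko, GbNa, GbCa;
  double maxsr, minsr, dmsr, EC2, k1p, k2p, k3, k4;
  double Vrel, Vleak, Vxfer, Vmaxup, Kup2;
  double Kbufc, BcKc, Kbufsr, BsrKsr, Kbufss, BssKss;
  double invVcF2C, invVcFC, invVssF2C, vsr_vc, vsr_vss, vc_vss;
};

static void step_nodes_scalar(int k0, int k1, const int* active, const int* nb,
                       double* const* S, double* V, const double* Vold,
                       const double* ENa, const double* EK,
                       const double* EKs, const double* ECa,
                       const double* gna, const double* gkr,
                       const double* gks, const double* istim, bool any_stim,
                       bool zero_ion, const Tables& T, const StepConsts& sp,
                       double t, char* activated, double* act_time,
                       const unsigned short* tile, const char* awake,
                       double* amax) {
  const double dt = sp.dt;
  for (int k = k0; k < k1; ++k) {
    int i = active[k];
    int ti = tile[i];
    if (!awake[ti]) continue;
    double v = Vold[i];
    double iion = 0.0;
    if (!zero_ion) {
      double cai = S[14][i], casr = S[15][i], cass = S[16][i], nai = S[17][i];
      const double *r0, *r1; double w;
      vlookup(T, v, r0, r1, w);
      double w0 = 1.0 - w;
      double tb[Tables::NCOL];
      for (int c = 0; c < Tables::NCOL; ++c)   // vectorizable interp
        tb[c] = r0[c] * w0 + r1[c] * w;
      // Rush-Larsen gate updates
      double m  = S[1][i] = tb[C_MINF] - (tb[C_MINF] - S[1][i]) * tb[C_MRL];
      double h  = S[2][i] = tb[C_HINF] - (tb[C_HINF] - S[2][i]) * tb[C_HRL];
      double jj = S[3][i] = tb[C_JINF] - (tb[C_JINF] - S[3][i]) * tb[C_JRL];
      double x1 = S[4][i] = tb[C_X1INF] - (tb[C_X1INF] - S[4][i]) * tb[C_X1RL];
      double x2 = S[5][i] = tb[C_X2INF] - (tb[C_X2INF] - S[5][i]) * tb[C_X2RL];
      double xs = S[6][i] = tb[C_XSINF] - (tb[C_XSINF] - S[6][i]) * tb[C_XSRL];
      double rg = S[7][i] = tb[C_RINF] - (tb[C_RINF] - S[7][i]) * tb[C_RRL];
      double sg = S[8][i] = tb[C_SINF] - (tb[C_SINF] - S[8][i]) * tb[C_SRL];
      double d  = S[9][i] = tb[C_DINF] - (tb[C_DINF] - S[9][i]) * tb[C_DRL];
      double f  = S[10][i] = tb[C_FINF] - (tb[C_FINF] - S[10][i]) * tb[C_FRL];
      double f2 = S[11][i] = tb[C_F2INF] - (tb[C_F2INF] - S[11][i]) * tb[C_F2RL];
      // All reciprocals of the algebraic subsystem are taken through one
      // batched inverse (divisions dominate the serial cost otherwise).
      double cKb = cai + sp.Kbufc, srKb = casr + sp.Kbufsr,
             ssKb = cass + sp.Kbufss;
      double cssr = cass * 20.0;               // cass / 0.05
      double den0 = 1.0 + cssr * cssr;         // fcass kinetics
      double den1 = nai + sp.KmNa;             // INaK saturation
      double den2 = sp.KpCa + cai;             // IpCa saturation
      double den3 = casr * casr + sp.EC2;      // SR release regulation
      double den4 = cai * cai + sp.Kup2;       // SERCA uptake
      double den5 = cKb * cKb + sp.BcKc;       // cytosolic buffering
      double den6 = srKb * srKb + sp.BsrKsr;   // SR buffering
      double den7 = ssKb * ssKb + sp.BssKss;   // subspace buffering
      double p01 = den0 * den1, p23 = den2 * den3;
      double p45 = den4 * den5, p67 = den6 * den7;
      double p03 = p01 * p23, p47 = p45 * p67;
      double invAll = 1.0 / (p03 * p47);
      double inv03 = invAll * p47, inv47 = invAll * p03;
      double inv01 = inv03 * p23, inv23 = inv03 * p01;
      double inv45 = inv47 * p67, inv67 = inv47 * p45;
      double i0 = inv01 * den1, i1 = inv01 * den0;
      double i2 = inv23 * den3, i3 = inv23 * den2;
      double i4 = inv45 * den5, i5 = inv45 * den4;
      double i6 = inv67 * den7, i7 = inv67 * den6;
      double fcinf = 0.6 * i0 + 0.4;
      double fctau = 80.0 * i0 + 2.0;
      double kcasr = sp.maxsr - sp.dmsr * (casr * casr) * i3;
      double css2 = cass * cass;
      double o_den = sp.k3 * kcasr + sp.k1p * css2;
      double q = 1.0 / (fctau * o_den);
      double fcass = S[12][i] += dt * (fcinf - S[12][i]) * (q * o_den);
      // currents (pA/pF)
      double ina = gna[i] * m * m * m * h * jj * (v - ENa[i]);
      double ical = d * f * f2 * fcass * (tb[C_PCAL] * cass - tb[C_QCAL]);
      double ito = sp.Gto * rg * sg * (v - EK[i]);
      double ikr = gkr[i] * sp.sqrtko * x1 * x2 * (v - EK[i]);
      double iks = gks[i] * xs * xs * (v - EKs[i]);
      double ik1 = k1lookup(T, v - EK[i]) * (v - EK[i]);
      double inaca = tb[C_ANACA] * nai * nai * nai - tb[C_BNACA] * cai;
      double inak = tb[C_FNAK] * nai * i1;
      double ipca = sp.GpCa * cai * i2;
      double ipk = tb[C_IPK] * (v - EK[i]);
      double ibna = sp.GbNa * (v - ENa[i]);
      double ibca = sp.GbCa * (v - ECa[i]);
      iion = ina + ical + ito + ikr + iks + ik1 + inaca + inak + ipca +
             ipk + ibna + ibca;
      // calcium subsystem
      double k2 = sp.k2p * kcasr;
      double rr = S[13][i];
      S[13][i] = rr + dt * (sp.k4 * (1.0 - rr) - k2 * cass * rr);
      double o = sp.k1p * css2 * rr * (q * fctau);
      double irel = sp.Vrel * o * (casr - cass);
      double ileak = sp.Vleak * (casr - cai);
      double iup = sp.Vmaxup * (cai * cai) * i4;
      double ixfer = sp.Vxfer * (cass - cai);
      double bc = cKb * cKb * i5, bsr = srKb * srKb * i6,
             bss = ssKb * ssKb * i7;
      S[14][i] = cai + dt * bc * (-(ibca + ipca - 2.0 * inaca) * sp.invVcF2C -
                                  (iup - ileak) * sp.vsr_vc + ixfer);
      S[15][i] = casr + dt * bsr * (iup - irel - ileak);
      S[16][i] = cass + dt * bss * (-ical * sp.invVssF2C + irel * sp.vsr_vss -
                                    ixfer * sp.vc_vss);
      S[17][i] = nai + dt * (-(ina + ibna + 3.0 * inak + 3.0 * inaca) *
                             sp.invVcFC);
      S[18][i] += dt * (-((any_stim ? istim[i] : 0.0) + ik1 + ito + ikr +
                          iks - 2.0 * inak + ipk) * sp.invVcFC);
    }
    // gap-junction coupling (explicit, from the previous time level)
    const int* nbi = &nb[4 * (size_t)i];
    double csum = 0.0;
    if (nbi[0] >= 0) csum += Vold[nbi[0]] - v;
    if (nbi[1] >= 0) csum += Vold[nbi[1]] - v;
    if (nbi[2] >= 0) csum += Vold[nbi[2]] - v;
    if (nbi[3] >= 0) csum += Vold[nbi[3]] - v;
    double vnew = v + dt * (sp.ccoup * csum - iion -
                            (any_stim ? istim[i] : 0.0));
    V[i] = vnew;
    double adv = vnew - v;
    if (adv < 0) adv = -adv;
    if (adv > amax[ti]) amax[ti] = adv;
    if (!activated[i] && v < sp.act_threshold && vnew >= sp.act_threshold) {
      activated[i] = 1;
      act_time[i] = t + dt;
    }
  }
}


// State column order shared with the R side.
// 1 V, 2 m, 3 h, 4 j, 5 xr1, 6 xr2, 7 xs, 8 r, 9 s, 10 d, 11 f, 12 f2,
// 13 fcass, 14 rr, 15 cai, 16 casr, 17 cass, 18 nai, 19 ki

// [[Rcpp::export(name = ".tp06_state_names")]]
CharacterVector tp06_state_names() {
  return CharacterVector::create("V", "m", "h", "j", "xr1", "xr2", "xs", "r",
                                 "s", "d", "f", "f2", "fcass", "rr", "cai",
                                 "casr", "cass", "nai", "ki");
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix state_in, int nrow, int ncol,
                 LogicalVector obstacle,
                 NumericVector gna, NumericVector gkr, NumericVector gks,
                 NumericVector params, double dt, int nsteps, double t0,
                 double ccoup,
                 List stim_idx, NumericVector stim_t0, NumericVector stim_dur,
                 NumericVector stim_amp,
                 IntegerVector probe_idx, int probe_stride,
                 int frame_stride,
                 NumericVector ecg_wx, NumericVector ecg_wy, int ecg_stride,
                 double act_threshold, int e_stride,
                 bool stop_all_quiet, double quiet_after,
                 IntegerVector stop_on_act,
                 bool zero_ion, double dx) {
  const int n = nrow * ncol;
  if (state_in.nrow() != n || state_in.ncol() != 19)
    stop("state must be a (nrow*ncol) x 19 matrix");
  P p = unpack(params);
  Tables T = build_tables(p, dt);
  NumericMatrix state = clone(state_in);
  double* S[19];
  for (int k = 0; k < 19; ++k) S[k] = &state(0, k);
  double* V = S[0];

  // connectivity: 4 von Neumann neighbor indices per node, -1 when the
  // edge crosses the boundary or touches an obstacle (no-flux)
  std::vector<int> nb(4 * (size_t)n, -1);
  std::vector<int> active;
  active.reserve(n);
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r) {
      int i = r + nrow * c;
      if (obstacle[i]) continue;
      active.push_back(i);
      if (r > 0        && !obstacle[i - 1])    nb[4 * (size_t)i + 0] = i - 1;
      if (r < nrow - 1 && !obstacle[i + 1])    nb[4 * (size_t)i + 1] = i + 1;
      if (c > 0        && !obstacle[i - nrow]) nb[4 * (size_t)i + 2] = i - nrow;
      if (c < ncol - 1 && !obstacle[i + nrow]) nb[4 * (size_t)i + 3] = i + nrow;
    }
  const int na = (int)active.size();
  if (na == 0) stop("grid has no myocyte nodes");

  // quiescence tiling: bands of 16 rows sleep while they and their
  // neighbor bands move by less than tile_eps mV per step.  Exactness
  // modes (zero_ion) keep every tile awake.
  const int tile_rows = 16;
  const double tile_eps = 5e-4 * dt;  // mV per step, dt-independent rate
  const int ntiles = (nrow + tile_rows - 1) / tile_rows;
  std::vector<unsigned short> tile(n);
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r)
      tile[r + (size_t)nrow * c] = (unsigned short)(r / tile_rows);
  std::vector<double> amax(ntiles, 1.0);   // start awake
  std::vector<char> awake(ntiles, 1);
  // a tile may sleep only after 250 consecutive sub-eps steps (5 ms at
  // dt = 0.02), so momentary turning points of V cannot freeze a tile
  const int quiet_need = 250;
  std::vector<int> quiet(ntiles, 0);

  std::vector<double> Vold(n), ENa(n, 0.0), EK(n, 0.0), EKs(n, 0.0), ECa(n, 0.0);
  const double rtf = p.RR * p.TT / p.FF;
  const double sqrtko = std::sqrt(p.Ko / 5.4);
  const double invVcF2C = p.Cap / (2.0 * p.Vc * p.FF);
  const double invVcFC  = p.Cap / (p.Vc * p.FF);
  const double invVssF2C = p.Cap / (2.0 * p.Vss * p.FF);
  const double vsr_vc = p.Vsr / p.Vc, vsr_vss = p.Vsr / p.Vss, vc_vss = p.Vc / p.Vss;
  StepConsts sp;
  sp.dt = dt; sp.ccoup = ccoup; sp.act_threshold = act_threshold;
  sp.Gto = p.Gto; sp.GpCa = p.GpCa; sp.KmNa = p.KmNa; sp.KpCa = p.KpCa;
  sp.sqrtko = sqrtko; sp.GbNa = p.GbNa; sp.GbCa = p.GbCa;
  sp.maxsr = p.maxsr; sp.minsr = p.minsr; sp.dmsr = p.maxsr - p.minsr;
  sp.EC2 = p.EC * p.EC; sp.k1p = p.k1p; sp.k2p = p.k2p; sp.k3 = p.k3;
  sp.k4 = p.k4; sp.Vrel = p.Vrel; sp.Vleak = p.Vleak; sp.Vxfer = p.Vxfer;
  sp.Vmaxup = p.Vmaxup; sp.Kup2 = p.Kup * p.Kup;
  sp.Kbufc = p.Kbufc; sp.BcKc = p.Bufc * p.Kbufc;
  sp.Kbufsr = p.Kbufsr; sp.BsrKsr = p.Bufsr * p.Kbufsr;
  sp.Kbufss = p.Kbufss; sp.BssKss = p.Bufss * p.Kbufss;
  sp.invVcF2C = invVcF2C; sp.invVcFC = invVcFC; sp.invVssF2C = invVssF2C;
  sp.vsr_vc = vsr_vc; sp.vsr_vss = vsr_vss; sp.vc_vss = vc_vss;

  // recording buffers
  const int np = probe_idx.size();
  int nprec = (probe_stride > 0) ? nsteps / probe_stride + 1 : 0;
  NumericMatrix probes(np > 0 ? nprec : 0, np);
  NumericVector probe_t(np > 0 ? nprec : 0);
  int nfrec = (frame_stride > 0) ? nsteps / frame_stride + 1 : 0;
  NumericMatrix frames(nfrec > 0 ? n : 0, nfrec);
  NumericVector frame_t(nfrec);
  bool do_ecg = ecg_wx.size() == n && ecg_stride > 0;
  int nerec = do_ecg ? nsteps / ecg_stride + 1 : 0;
  NumericVector ecg(nerec), ecg_t(nerec);
  NumericVector act_time(n, NA_REAL);
  std::vector<char> activated(n, 0);

  const int nstim = stim_idx.size();
  std::vector<std::vector<int>> sidx(nstim);
  for (int s = 0; s < nstim; ++s) sidx[s] = as<std::vector<int>>(stim_idx[s]);
  std::vector<std::vector<char>> stim_tiles(nstim,
                                            std::vector<char>(ntiles, 0));
  for (int s = 0; s < nstim; ++s)
    for (size_t q = 0; q < sidx[s].size(); ++q)
      stim_tiles[s][tile[sidx[s][q]]] = 1;
  std::vector<double> istim(n, 0.0);

  int ip = 0, ifr = 0, ie = 0;
  double stop_time = NA_REAL;
  std::string stop_reason = "completed";
  bool stopped = false;

  auto record = [&](int step, double t) {
    if (np > 0 && probe_stride > 0 && step % probe_stride == 0 && ip < nprec) {
      for (int q = 0; q < np; ++q) probes(ip, q) = V[probe_idx[q]];
      probe_t[ip++] = t;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifr < nfrec) {
      std::memcpy(&frames(0, ifr), V, sizeof(double) * n);
      frame_t[ifr++] = t;
    }
    if (do_ecg && step % ecg_stride == 0 && ie < nerec) {
      double acc = 0.0;
      const double inv2dx = 1.0 / (2.0 * dx), invdx = 1.0 / dx;
      for (int k = 0; k < na; ++k) {
        int i = active[k];
        const int* nbi = &nb[4 * (size_t)i];
        double gx, gy;
        // rows advance along x (index step 1), columns along y
        if (nbi[0] >= 0 && nbi[1] >= 0) gx = (V[nbi[1]] - V[nbi[0]]) * inv2dx;
        else if (nbi[1] >= 0) gx = (V[nbi[1]] - V[i]) * invdx;
        else if (nbi[0] >= 0) gx = (V[i] - V[nbi[0]]) * invdx;
        else gx = 0.0;
        if (nbi[2] >= 0 && nbi[3] >= 0) gy = (V[nbi[3]] - V[nbi[2]]) * inv2dx;
        else if (nbi[3] >= 0) gy = (V[nbi[3]] - V[i]) * invdx;
        else if (nbi[2] >= 0) gy = (V[i] - V[nbi[2]]) * invdx;
        else gy = 0.0;
        acc += ecg_wx[i] * gx + ecg_wy[i] * gy;
      }
      ecg[ie] = acc;
      ecg_t[ie++] = t;
    }
  };

  record(0, t0);

  for (int step = 0; step < nsteps && !stopped; ++step) {
    double t = t0 + step * dt;
    if (step % e_stride == 0) {
      for (int k = 0; k < na; ++k) {
        int i = active[k];
        if (!awake[tile[i]] && step > 0) continue;
        ENa[i] = rtf * std::log(p.Nao / S[17][i]);
        EK[i]  = rtf * std::log(p.Ko / S[18][i]);
        EKs[i] = rtf * std::log((p.Ko + p.pKNa * p.Nao) /
                                (S[18][i] + p.pKNa * S[17][i]));
        ECa[i] = 0.5 * rtf * std::log(p.Cao / S[14][i]);
      }
    }
    // stimulus currents for this step
    bool any_stim = false;
    std::vector<char> stim_wake(ntiles, 0);
    for (int s = 0; s < nstim; ++s)
      if (t >= stim_t0[s] - 1e-9 && t < stim_t0[s] + stim_dur[s] - 1e-9) {
        if (!any_stim) std::fill(istim.begin(), istim.end(), 0.0);
        any_stim = true;
        for (size_t q = 0; q < sidx[s].size(); ++q) istim[sidx[s][q]] += stim_amp[s];
        for (int q = 0; q < ntiles; ++q)
          if (stim_tiles[s][q]) stim_wake[q] = 1;
      }

    // a tile sleeps only when it and its neighbor bands have been
    // persistently quiet and no stimulus is aimed at it
    for (int q = 0; q < ntiles; ++q)
      if (stim_wake[q]) quiet[q] = 0;
    for (int q = 0; q < ntiles; ++q) {
      bool rested = quiet[q] >= quiet_need &&
                    (q == 0 || quiet[q - 1] >= quiet_need) &&
                    (q == ntiles - 1 || quiet[q + 1] >= quiet_need);
      awake[q] = (zero_ion || !rested) ? 1 : 0;
    }
    for (int q = 0; q < ntiles; ++q) if (awake[q]) amax[q] = 0.0;

    std::memcpy(Vold.data(), V, sizeof(double) * n);

    step_nodes_scalar(0, na, active.data(), nb.data(), S, V, Vold.data(),
                      ENa.data(), EK.data(), EKs.data(), ECa.data(),
                      REAL(gna), REAL(gkr), REAL(gks), istim.data(),
                      any_stim, zero_ion, T, sp, t, activated.data(),
                      act_time.begin(), tile.data(), awake.data(),
                      amax.data());
    for (int q = 0; q < ntiles; ++q)
      if (awake[q]) quiet[q] = (amax[q] < tile_eps) ? quiet[q] + 1 : 0;

    double tnext = t0 + (step + 1) * dt;
    record(step + 1, tnext);

    // early exits, checked every 10 ms
    if (step % 500 == 499) {
      if (!std::isfinite(V[active[0]])) {
        for (int k = 0; k < na; ++k)
          if (!std::isfinite(V[active[k]]))
            stop("non-finite voltage at node %d (t = %f ms)", active[k] + 1, tnext);
      }
      if (stop_all_quiet && tnext >= quiet_after) {
        bool quiet = true;
        for (int k = 0; k < na; ++k)
          if (V[active[k]] >= act_threshold) { quiet = false; break; }
        if (quiet) { stopped = true; stop_time = tnext; stop_reason = "all_quiet"; }
      }
      if (!stopped && stop_on_act.size() > 0) {
        for (int q = 0; q < stop_on_act.size(); ++q)
          if (activated[stop_on_act[q]]) {
            stopped = true; stop_time = tnext; stop_reason = "target_activated";
            break;
          }
      }
    }
  }
  // final NaN check
  for (int k = 0; k < na; ++k)
    if (!std::isfinite(V[active[k]]))
      stop("non-finite voltage at node %d (end of run)", active[k] + 1);

  return List::create(
      _["state"] = state,
      _["probes"] = probes, _["probe_t"] = probe_t,
      _["frames"] = frames, _["frame_t"] = frame_t,
      _["ecg"] = ecg, _["ecg_t"] = ecg_t,
      _["act_time"] = act_time,
      _["stopped"] = stopped, _["stop_time"] = stop_time,
      _["stop_reason"] = stop_reason,
      _["n_recorded"] = IntegerVector::create(_["probes"] = ip, _["frames"] = ifr,
                                              _["ecg"] = ie));
}

// Single-cell TP06 right-hand side at a point, for diagnostics and
// cross-checks; returns d(state)/dt including dV/dt (no coupling).
// [[Rcpp::export(name = ".tp06_derivs_cpp")]]
NumericVector tp06_derivs_cpp(NumericVector y, NumericVector params,
                              double istim) {
  P p = unpack(params);
  for (int k = 0; k < y.size(); ++k)
    if (!std::isfinite(y[k]))
      stop("non-finite state variable '%s'",
           std::string(as<CharacterVector>(tp06_state_names())[k]));
  double v = y[0], m = y[1], h = y[2], jj = y[3], x1 = y[4], x2 = y[5],
         xs = y[6], rg = y[7], sg = y[8], d = y[9], f = y[10], f2 = y[11],
         fcass = y[12], rr = y[13], cai = y[14], casr = y[15], cass = y[16],
         nai = y[17], ki = y[18];
  double rtf = p.RR * p.TT / p.FF;
  double ena = rtf * std::log(p.Nao / nai), ek = rtf * std::log(p.Ko / ki);
  double eks = rtf * std::log((p.Ko + p.pKNa * p.Nao) / (ki + p.pKNa * nai));
  double eca = 0.5 * rtf * std::log(p.Cao / cai);
  Rates g;
  gate_rates(v, p, g);
  double x = 2.0 * (v - 15.0) * p.FF / (p.RR * p.TT);
  double ical;
  if (std::fabs(x) < 1e-7)
    ical = d * f * f2 * fcass * p.GCaL * 2.0 * p.FF * (0.25 * cass - p.Cao);
  else
    ical = d * f * f2 * fcass * p.GCaL * 4.0 * (v - 15.0) * p.FF * p.FF /
           (p.RR * p.TT) * (0.25 * cass * std::exp(x) - p.Cao) / std::expm1(x);
  double ina = p.GNa * m * m * m * h * jj * (v - ena);
  double ito = p.Gto * rg * sg * (v - ek);
  double ikr = p.GKr * std::sqrt(p.Ko / 5.4) * x1 * x2 * (v - ek);
  double iks = p.GKs * xs * xs * (v - eks);
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (v - ek - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (v - ek + 100.0)) +
                std::exp(0.1 * (v - ek - 10.0))) /
               (1.0 + std::exp(-0.5 * (v - ek)));
  double ik1 = p.GK1 * ak1 / (ak1 + bk1) * (v - ek);
  double den = (p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao) *
               (p.KmCa + p.Cao) *
               (1.0 + p.ksat * std::exp((p.ngamma - 1.0) * v / rtf));
  double inaca = p.knaca *
                 (std::exp(p.ngamma * v / rtf) * nai * nai * nai * p.Cao -
                  std::exp((p.ngamma - 1.0) * v / rtf) * p.Nao * p.Nao * p.Nao *
                      cai * 2.5) / den;
  double inak = p.PNaK * (p.Ko / (p.Ko + p.KmK)) * (nai / (nai + p.KmNa)) /
                (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                 0.0353 * std::exp(-v / rtf));
  double ipca = p.GpCa * cai / (p.KpCa + cai);
  double ipk = p.GpK * (v - ek) / (1.0 + std::exp((25.0 - v) / 5.98));
  double ibna = p.GbNa * (v - ena);
  double ibca = p.GbCa * (v - eca);
  double iion = ina + ical + ito + ikr + iks + ik1 + inaca + inak + ipca +
                ipk + ibna + ibca;
  double kcasr = p.maxsr - (p.maxsr - p.minsr) /
                 (1.0 + (p.EC / casr) * (p.EC / casr));
  double k1 = p.k1p / kcasr, k2 = p.k2p * kcasr;
  double drr = p.k4 * (1.0 - rr) - k2 * cass * rr;
  double o = k1 * cass * cass * rr / (p.k3 + k1 * cass * cass);
  double irel = p.Vrel * o * (casr - cass);
  double ileak = p.Vleak * (casr - cai);
  double iup = p.Vmaxup / (1.0 + (p.Kup * p.Kup) / (cai * cai));
  double ixfer = p.Vxfer * (cass - cai);
  double bc = 1.0 / (1.0 + p.Bufc * p.Kbufc / ((cai + p.Kbufc) * (cai + p.Kbufc)));
  double bsr = 1.0 / (1.0 + p.Bufsr * p.Kbufsr / ((casr + p.Kbufsr) * (casr + p.Kbufsr)));
  double bss = 1.0 / (1.0 + p.Bufss * p.Kbufss / ((cass + p.Kbufss) * (cass + p.Kbufss)));
  double css_r = cass / 0.05;
  double fc_den = 1.0 / (1.0 + css_r * css_r);
  double fcinf = 0.6 * fc_den + 0.4, fctau = 80.0 * fc_den + 2.0;
  NumericVector dy(19);
  dy[0] = -(iion + istim);
  dy[1] = (g.inf[0] - m) / g.tau[0];
  dy[2] = (g.inf[1] - h) / g.tau[1];
  dy[3] = (g.inf[2] - jj) / g.tau[2];
  dy[4] = (g.inf[3] - x1) / g.tau[3];
  dy[5] = (g.inf[4] - x2) / g.tau[4];
  dy[6] = (g.inf[5] - xs) / g.tau[5];
  dy[7] = (g.inf[6] - rg) / g.tau[6];
  dy[8] = (g.inf[7] - sg) / g.tau[7];
  dy[9] = (g.inf[8] - d) / g.tau[8];
  dy[10] = (g.inf[9] - f) / g.tau[9];
  dy[11] = (g.inf[10] - f2) / g.tau[10];
  dy[12] = (fcinf - fcass) / fctau;
  dy[13] = drr;
  dy[14] = bc * (-(ibca + ipca - 2.0 * inaca) * p.Cap / (2.0 * p.Vc * p.FF) -
                 (iup - ileak) * p.Vsr / p.Vc + ixfer);
  dy[15] = bsr * (iup - irel - ileak);
  dy[16] = bss * (-ical * p.Cap / (2.0 * p.Vss * p.FF) + irel * p.Vsr / p.Vss -
                  ixfer * p.Vc / p.Vss);
  dy[17] = -(ina + ibna + 3.0 * inak + 3.0 * inaca) * p.Cap / (p.Vc * p.FF);
  dy[18] = -(istim + ik1 + ito + ikr + iks - 2.0 * inak + ipk) * p.Cap /
           (p.Vc * p.FF);
  dy.attr("names") = tp06_state_names();
  return dy;
}

// Phase-singularity detection by winding number of the time-delay
// embedding phase theta = atan2(V(t) - Vstar, V(t - tau) - Vstar) around
// each unit plaquette.  Plaquettes touching obstacles are skipped.
// [[Rcpp::export(name = ".detect_ps_cpp")]]
DataFrame detect_ps_cpp(NumericVector v1, NumericVector v0, int nrow, int ncol,
                        LogicalVector obstacle, double vstar) {
  if (v1.size() != nrow * ncol || v0.size() != nrow * ncol)
    stop("frame size does not match grid dimensions");
  std::vector<double> th((size_t)nrow * ncol);
  for (int i = 0; i < nrow * ncol; ++i)
    th[i] = std::atan2(v1[i] - vstar, v0[i] - vstar);
  std::vector<double> row, col, charge;
  const double twopi = 2.0 * M_PI;
  for (int c = 0; c < ncol - 1; ++c)
    for (int r = 0; r < nrow - 1; ++r) {
      int i00 = r + nrow * c, i10 = i00 + 1, i11 = i10 + nrow, i01 = i00 + nrow;
      if (obstacle[i00] || obstacle[i10] || obstacle[i11] || obstacle[i01])
        continue;
      double w = 0.0, d;
      d = th[i10] - th[i00]; if (d > M_PI) d -= twopi; else if (d < -M_PI) d += twopi; w += d;
      d = th[i11] - th[i10]; if (d > M_PI) d -= twopi; else if (d < -M_PI) d += twopi; w += d;
      d = th[i01] - th[i11]; if (d > M_PI) d -= twopi; else if (d < -M_PI) d += twopi; w += d;
      d = th[i00] - th[i01]; if (d > M_PI) d -= twopi; else if (d < -M_PI) d += twopi; w += d;
      if (std::fabs(w) > M_PI) {  // winding of +-2*pi
        row.push_back(r + 1.5);   // 1-based plaquette center
        col.push_back(c + 1.5);
        charge.push_back(w > 0 ? 1.0 : -1.0);
      }
    }
  return DataFrame::create(_["row"] = row, _["col"] = col, _["charge"] = charge);
}
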