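// Fixed-step simulation core: explicit second-order Runge-Kutta endpoint
// (modified Euler) integration of the cell models, with threshold-clamp-reset
// spiking for integrate-and-fire type cells and upward zero-crossing spike
// detection for the Hodgkin-Huxley type cells.
//
// Units package-wide: mV, ms, uA/cm2, mS/cm2, uF/cm2.
//
// Noise: one Gaussian draw per cell per step, entering the voltage equation
// as g_N * eta (uA/cm2) in BOTH RK2 stages; not scaled by sqrt(dt). Streams
// are keyed by (master_seed, cell_id, trial_id) through splitmix64 so every
// cell/trial pair is independent and bit-reproducible across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <map>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ------

static inline uint64_t splitmix64_next(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct GaussRNG {
  uint64_t state;
  bool has_spare;
  double spare;
  GaussRNG() : state(0), has_spare(false), spare(0.0) {}
  void seed3(uint64_t a, uint64_t b, uint64_t c) {
    // mix the three keys through successive splitmix steps
    uint64_t s = a;
    (void)splitmix64_next(s);
    s ^= 0x9E3779B97F4A7C15ULL * (b + 1);
    (void)splitmix64_next(s);
    s ^= 0xBF58476D1CE4E5B9ULL * (c + 1);
    (void)splitmix64_next(s);
    state = s;
    has_spare = false;
  }
  double unif() {
    return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = m * std::sin(a);
    has_spare = true;
    return m * std::cos(a);
  }
};

// ------------------------------------------------------- gating kinetics ---

// a*(V+c) / (1 - exp(-(V+c)/b)) with the removable singularity at V = -c
// evaluated as the limit a*b.
static inline double vtrap(double a, double V, double c, double b) {
  double x = V + c;
  if (std::fabs(x) < 1e-7) return a * b;
  return a * x / (1.0 - std::exp(-x / b));
}

// a*x / (exp(x/b) - 1) with limit a*b at x = 0 (used for beta_m of the PYR).
static inline double vtrap2(double a, double x, double b) {
  if (std::fabs(x) < 1e-7) return a * b;
  return a * x / (std::exp(x / b) - 1.0);
}

static inline double hsyn(double V) { return 0.5 * (1.0 + std::tanh(V / 4.0)); }

// persistent sodium / h-current model
static inline double naph_pinf(double V) { return 1.0 / (1.0 + std::exp(-(V + 38.0) / 6.5)); }
static inline double naph_rinf(double V) { return 1.0 / (1.0 + std::exp((V + 79.2) / 9.78)); }

// Gate kinetics of the biophysical cells are evaluated with the voltage
// argument confined to the physical domain [-120, 60] mV: RK2 predictor
// states can overshoot far beyond it during the spike upstroke, where the
// gating time constants underflow and destabilize the explicit update.
static inline double vclamp(double V) {
  return V < -120.0 ? -120.0 : (V > 60.0 ? 60.0 : V);
}

// 4D pyramidal cell
static inline void pyr_hn(double V, double &hinf, double &tauh,
                          double &ninf, double &taun) {
  V = vclamp(V);
  double ah = 0.128 * std::exp(-(V + 50.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
  hinf = ah / (ah + bh); tauh = 1.0 / (ah + bh);
  double an = vtrap(0.032, V, 52.0, 5.0);
  double bn = 0.5 * std::exp(-(V + 57.0) / 40.0);
  ninf = an / (an + bn); taun = 1.0 / (an + bn);
}
static inline double pyr_minf(double V) {
  V = vclamp(V);
  double am = vtrap(0.32, V, 54.0, 4.0);
  double bm = vtrap2(0.28, V + 27.0, 5.0);
  return am / (am + bm);
}
static inline void pyr_r(double V, double &rinf, double &taur) {
  V = vclamp(V);
  rinf = 1.0 / (1.0 + std::exp((V + 82.9) / 12.4));
  taur = 136.36 * std::exp(0.033 * (V + 75.0)) / (1.0 + std::exp(0.083 * (V + 75.0)));
}

// Wang-Buzsaki interneuron with M-like current
static inline void int_hn(double V, double &hinf, double &tauh,
                          double &ninf, double &taun) {
  V = vclamp(V);
  double ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(V + 28.0) / 10.0));
  hinf = ah / (ah + bh); tauh = 0.2 / (ah + bh);
  double an = vtrap(0.01, V, 34.0, 10.0);
  double bn = 0.125 * std::exp(-(V + 44.0) / 80.0);
  ninf = an / (an + bn); taun = 0.2 / (an + bn);
}
static inline double int_minf(double V) {
  V = vclamp(V);
  double am = vtrap(0.2, V, 35.0, 10.0);
  double bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
  return am / (am + bm);
}
static inline void int_q(double V, double &qinf, double &tauq) {
  V = vclamp(V);
  qinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  tauq = 40.0 / (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
}

// ------------------------------------------------------------ model RHS ----
// Model ids:
//  1 lif             p = C,gL,EL                              y = V
//  2 naph            p = C,gL,EL,gp,ENa,gh,Eh,taur            y = V,r
//  3 calcium_lif     p = C,gL,EL,gC,ECa,tact,tinact,tdeact    y = V,K,NC
//  4 plastic_lif     p = C,gL,EL,gS,ES,tr,td,tresd,tdep,      y = V,S,D,F
//                        tresf,tfac,use_dep,use_fac           (Vpre-driven)
//  5 pyr             p = C,gL,EL,gNa,ENa,gK,EK,gh,Eh          y = V,h,n,r
//  6 wb_int          p = C,gL,EL,gNa,ENa,gK,EK,gM             y = V,h,n,q
// I is the total applied current (stimulus + noise); I_syn is an additional
// synaptic current already evaluated at the caller's V (subtracted here).

static inline void model_rhs(int model, const double *p, const double *y,
                             double I, double Vpre, double Isyn, double *dy,
                             double Rel = 1.0) {
  double V = y[0];
  switch (model) {
  case 1: { // lif
    dy[0] = (I - p[1] * (V - p[2]) - Isyn) / p[0];
  } break;
  case 2: { // naph
    double r = y[1];
    dy[0] = (I - p[1] * (V - p[2]) - p[3] * naph_pinf(V) * (V - p[4])
             - p[5] * r * (V - p[6]) - Isyn) / p[0];
    dy[1] = (naph_rinf(V) - r) / p[7];
  } break;
  case 3: { // calcium lif
    double K = y[1], NC = y[2];
    dy[0] = (I - p[1] * (V - p[2]) - p[3] * K * (V - p[4]) - Isyn) / p[0];
    dy[1] = NC * (1.0 - K) / p[5] - K / p[6];
    dy[2] = -NC / p[7];
  } break;
  case 4: { // lif with plastic synapse, driven by presynaptic voltage.
    // Rel is the release probability D*F sampled at the onset of the
    // current presynaptic pulse: depression/facilitation triggered by a
    // spike affect subsequent spikes, not the concurrent release.
    double S = y[1], D = y[2], F = y[3];
    double hv = hsyn(Vpre);
    bool use_dep = p[11] != 0.0, use_fac = p[12] != 0.0;
    dy[0] = (I - p[1] * (V - p[2]) - p[3] * S * Rel * (V - p[4]) - Isyn) / p[0];
    dy[1] = hv * (1.0 - S) / p[5] - S / p[6];
    dy[2] = use_dep ? (-hv * D / p[7] + (1.0 - D) / p[8]) : 0.0;
    dy[3] = use_fac ? (hv * (1.0 - F) / p[9] - F / p[10]) : 0.0;
  } break;
  case 5: { // pyr
    double h = y[1], n = y[2], r = y[3];
    double hinf, tauh, ninf, taun, rinf, taur;
    pyr_hn(V, hinf, tauh, ninf, taun);
    pyr_r(V, rinf, taur);
    double m = pyr_minf(V);
    double n2 = n * n;
    dy[0] = (I - p[1] * (V - p[2]) - p[3] * h * m * m * m * (V - p[4])
             - p[5] * n2 * n2 * (V - p[6]) - p[7] * r * (V - p[8]) - Isyn) / p[0];
    dy[1] = (hinf - h) / tauh;
    dy[2] = (ninf - n) / taun;
    dy[3] = (rinf - r) / taur;
  } break;
  case 6: { // wb interneuron + M-like current
    double h = y[1], n = y[2], q = y[3];
    double hinf, tauh, ninf, taun, qinf, tauq;
    int_hn(V, hinf, tauh, ninf, taun);
    int_q(V, qinf, tauq);
    double m = int_minf(V);
    double n2 = n * n;
    dy[0] = (I - p[1] * (V - p[2]) - p[3] * h * m * m * m * (V - p[4])
             - p[5] * n2 * n2 * (V - p[6]) - p[7] * q * (V - p[6]) - Isyn) / p[0];
    dy[1] = (hinf - h) / tauh;
    dy[2] = (ninf - n) / taun;
    dy[3] = (qinf - q) / tauq;
  } break;
  default:
    stop("unknown model id %d", model);
  }
}

static inline int model_nstate(int model) {
  switch (model) {
  case 1: return 1;
  case 2: return 2;
  case 3: return 3;
  case 4: return 4;
  case 5: return 4;
  case 6: return 4;
  }
  return 0;
}

static inline bool is_if_type(int model) { return model <= 4; }

static void check_finite(double V, const char *what, int cell) {
  if (!std::isfinite(V))
    stop("simulation diverged: non-finite membrane potential (%s, cell %d)", what, cell);
  if (std::fabs(V) > 200.0)
    stop("simulation diverged: |V| > 200 mV (%s, cell %d)", what, cell);
}

// [[Rcpp::export(name = ".sim_cell_cpp")]]
List sim_cell_cpp(int model, NumericVector par, NumericVector spikepar,
                  NumericVector I_ext, NumericVector Vpre, NumericVector y0,
                  double dt, double sigma, double gN,
                  double master_seed, double cell_id, double trial_id,
                  bool record_v, bool record_aux, int arm_after = 0) {
  const int ns = model_nstate(model);
  const int nsteps = I_ext.size() - 1;
  if (nsteps < 1) stop("stimulus must contain at least two samples");
  const bool has_vpre = Vpre.size() == I_ext.size();
  if (model == 4 && !has_vpre)
    stop("plastic-synapse model requires a presynaptic voltage trace on the same grid");

  // spike mechanism (integrate-and-fire models)
  double Vth = spikepar[0], Vreset = spikepar[1], Vpeak = spikepar[2];
  int nclamp = (int)std::lround(spikepar[3] / dt);
  if (nclamp < 1) nclamp = 1;
  double NCreset = spikepar.size() > 4 ? spikepar[4] : NA_REAL;

  GaussRNG rng;
  rng.seed3((uint64_t)master_seed, (uint64_t)cell_id, (uint64_t)trial_id);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), ypred(ns);
  std::vector<double> spikes;
  NumericVector Vrec;
  NumericMatrix auxrec;
  if (record_v) Vrec = NumericVector(nsteps + 1);
  if (record_aux && ns > 1) auxrec = NumericMatrix(nsteps + 1, ns - 1);
  if (record_v) Vrec[0] = y[0];
  if (record_aux && ns > 1)
    for (int j = 1; j < ns; ++j) auxrec(0, j - 1) = y[j];

  int clamp = 0;

  // release probability, re-sampled from D*F at each presynaptic pulse onset
  bool use_dep = (model == 4) && par[11] != 0.0;
  bool use_fac = (model == 4) && par[12] != 0.0;
  double Rel = (use_fac ? y[3] : 1.0) * (use_dep ? y[2] : 1.0);

  for (int n = 0; n < nsteps; ++n) {
    double eta = (sigma > 0.0) ? sigma * rng.norm() : 0.0;
    double I1 = I_ext[n] + gN * eta;
    double I2 = I_ext[n + 1] + gN * eta;
    double Vp1 = has_vpre ? Vpre[n] : -60.0;
    double Vp2 = has_vpre ? Vpre[n + 1] : -60.0;
    // sample the release BEFORE the pulse first enters either RK2 stage
    if (model == 4 && ((Vp2 > 0.0 && Vp1 <= 0.0) || (n == 0 && Vp1 > 0.0)))
      Rel = (use_dep ? y[2] : 1.0) * (use_fac ? y[3] : 1.0);

    if (clamp > 0) {
      // V held at Vpeak; auxiliary states keep evolving with V = Vpeak
      model_rhs(model, REAL(par), y.data(), I1, Vp1, 0.0, k1.data(), Rel);
      ypred[0] = y[0];
      for (int j = 1; j < ns; ++j) ypred[j] = y[j] + dt * k1[j];
      model_rhs(model, REAL(par), ypred.data(), I2, Vp2, 0.0, k2.data(), Rel);
      for (int j = 1; j < ns; ++j) {
        y[j] += 0.5 * dt * (k1[j] + k2[j]);
        if (y[j] < 0.0) y[j] = 0.0; else if (y[j] > 1.0) y[j] = 1.0;
      }
      if (--clamp == 0) {
        y[0] = Vreset;
        if (model == 3 && R_finite(NCreset)) y[2] = NCreset;
      }
    } else {
      model_rhs(model, REAL(par), y.data(), I1, Vp1, 0.0, k1.data(), Rel);
      for (int j = 0; j < ns; ++j) ypred[j] = y[j] + dt * k1[j];
      model_rhs(model, REAL(par), ypred.data(), I2, Vp2, 0.0, k2.data(), Rel);
      double Vold = y[0];
      y[0] += 0.5 * dt * (k1[0] + k2[0]);
      for (int j = 1; j < ns; ++j) {
        y[j] += 0.5 * dt * (k1[j] + k2[j]);
        if (y[j] < 0.0) y[j] = 0.0; else if (y[j] > 1.0) y[j] = 1.0;
      }
      check_finite(y[0], "cell", 1);
      if (is_if_type(model) && n >= arm_after) {
        if (y[0] > Vth) {
          spikes.push_back((n + 1) * dt);
          y[0] = Vpeak;
          clamp = nclamp;
        }
      } else {
        if (Vold < 0.0 && y[0] >= 0.0) spikes.push_back((n + 1) * dt);
      }
    }

    if (record_v) Vrec[n + 1] = y[0];
    if (record_aux && ns > 1)
      for (int j = 1; j < ns; ++j) auxrec(n + 1, j - 1) = y[j];
  }

  List out = List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["state"] = NumericVector(y.begin(), y.end()));
  if (record_v) out["V"] = Vrec;
  if (record_aux && ns > 1) out["aux"] = auxrec;
  return out;
}

// [[Rcpp::export(name = ".noise_steps_cpp")]]
NumericVector noise_steps_cpp(double sigma, int n, double gN,
                              double master_seed, double cell_id, double trial_id) {
  GaussRNG rng;
  rng.seed3((uint64_t)master_seed, (uint64_t)cell_id, (uint64_t)trial_id);
  NumericVector out(n);
  if (sigma > 0.0)
    for (int i = 0; i < n; ++i) out[i] = gN * sigma * rng.norm();
  return out;
}

// ------------------------------------------------- E/I all-to-all network --
// Ne excitatory cells (model 1 or 2), Ni inhibitory LIF cells. One synaptic
// gate per presynaptic cell, driven by that cell's own voltage. Total
// synaptic currents follow the all-to-all class-conductance formalism.

// [[Rcpp::export(name = ".sim_ei_cpp")]]
List sim_ei_cpp(int e_model, int Ne, int Ni,
                NumericVector epar, NumericVector espike,
                NumericVector ipar, NumericVector ispike,
                NumericVector syn, // gee,gei,gie,gii,Ee,Ei,tre,tde,tri,tdi
                NumericVector Ie, NumericVector Ii,
                double sig_e, double sig_i, double gN,
                double dt, double master_seed, double trial_id,
                IntegerVector record_cells, int arm_after,
                NumericVector ye0, double vi0) {
  const int nsteps = Ie.size() - 1;
  if (Ii.size() != Ie.size()) stop("E and I stimulus grids differ");
  const int nse = model_nstate(e_model);
  if (e_model != 1 && e_model != 2) stop("E-cells must be lif or naph");
  const double gee = syn[0], gei = syn[1], gie = syn[2], gii = syn[3];
  const double Ee = syn[4], Ei = syn[5];
  const double tre = syn[6], tde = syn[7], tri = syn[8], tdi = syn[9];

  const double eVth = espike[0], eVreset = espike[1], eVpeak = espike[2];
  const double iVth = ispike[0], iVreset = ispike[1], iVpeak = ispike[2];
  int enclamp = std::max(1, (int)std::lround(espike[3] / dt));
  int inclamp = std::max(1, (int)std::lround(ispike[3] / dt));

  // states
  std::vector<std::vector<double>> ye(Ne, std::vector<double>(nse));
  std::vector<double> Se(Ne, 0.0), Vi(Ni), Si(Ni, 0.0);
  std::vector<int> eclamp(Ne, 0), iclamp(Ni, 0);
  std::vector<GaussRNG> rng(Ne + Ni);
  for (int c = 0; c < Ne; ++c) {
    for (int j = 0; j < nse; ++j) ye[c][j] = ye0[j];
    rng[c].seed3((uint64_t)master_seed, (uint64_t)(c + 1), (uint64_t)trial_id);
  }
  for (int c = 0; c < Ni; ++c) {
    Vi[c] = vi0;
    rng[Ne + c].seed3((uint64_t)master_seed, (uint64_t)(Ne + c + 1), (uint64_t)trial_id);
  }

  std::vector<std::vector<double>> spikes(Ne + Ni);
  std::map<int, NumericVector> vrec;
  for (int k = 0; k < record_cells.size(); ++k)
    vrec[record_cells[k]] = NumericVector(nsteps + 1);
  for (auto &kv : vrec) {
    int c = kv.first;
    kv.second[0] = (c <= Ne) ? ye[c - 1][0] : Vi[c - Ne - 1];
  }

  std::vector<double> etaE(Ne), etaI(Ni);
  std::vector<std::vector<double>> k1e(Ne, std::vector<double>(nse)),
      k2e(Ne, std::vector<double>(nse)), yep(Ne, std::vector<double>(nse));
  std::vector<double> k1Se(Ne), k2Se(Ne), Sep(Ne);
  std::vector<double> k1Vi(Ni), k2Vi(Ni), Vip(Ni), k1Si(Ni), k2Si(Ni), Sip(Ni);

  for (int n = 0; n < nsteps; ++n) {
    for (int c = 0; c < Ne; ++c) etaE[c] = (sig_e > 0) ? sig_e * rng[c].norm() : 0.0;
    for (int c = 0; c < Ni; ++c) etaI[c] = (sig_i > 0) ? sig_i * rng[Ne + c].norm() : 0.0;

    double sumSe = 0.0, sumSi = 0.0;
    for (int c = 0; c < Ne; ++c) sumSe += Se[c];
    for (int c = 0; c < Ni; ++c) sumSi += Si[c];

    // stage 1
    for (int c = 0; c < Ne; ++c) {
      double V = ye[c][0];
      double Isyn = gee * sumSe * (V - Ee) + gei * sumSi * (V - Ei);
      model_rhs(e_model, REAL(epar), ye[c].data(), Ie[n] + gN * etaE[c], -60.0,
                Isyn, k1e[c].data());
      if (eclamp[c] > 0) k1e[c][0] = 0.0;
      k1Se[c] = hsyn(V) * (1.0 - Se[c]) / tre - Se[c] / tde;
      for (int j = 0; j < nse; ++j) yep[c][j] = ye[c][j] + dt * k1e[c][j];
      Sep[c] = Se[c] + dt * k1Se[c];
    }
    for (int c = 0; c < Ni; ++c) {
      double V = Vi[c];
      double Isyn = gie * sumSe * (V - Ee) + gii * sumSi * (V - Ei);
      k1Vi[c] = (iclamp[c] > 0) ? 0.0
        : (Ii[n] + gN * etaI[c] - ipar[1] * (V - ipar[2]) - Isyn) / ipar[0];
      k1Si[c] = hsyn(V) * (1.0 - Si[c]) / tri - Si[c] / tdi;
      Vip[c] = V + dt * k1Vi[c];
      Sip[c] = Si[c] + dt * k1Si[c];
    }

    // stage 2 on the predictor states
    double sumSe2 = 0.0, sumSi2 = 0.0;
    for (int c = 0; c < Ne; ++c) sumSe2 += Sep[c];
    for (int c = 0; c < Ni; ++c) sumSi2 += Sip[c];
    for (int c = 0; c < Ne; ++c) {
      double V = yep[c][0];
      double Isyn = gee * sumSe2 * (V - Ee) + gei * sumSi2 * (V - Ei);
      model_rhs(e_model, REAL(epar), yep[c].data(), Ie[n + 1] + gN * etaE[c], -60.0,
                Isyn, k2e[c].data());
      if (eclamp[c] > 0) k2e[c][0] = 0.0;
      k2Se[c] = hsyn(V) * (1.0 - Sep[c]) / tre - Sep[c] / tde;
    }
    for (int c = 0; c < Ni; ++c) {
      double V = Vip[c];
      double Isyn = gie * sumSe2 * (V - Ee) + gii * sumSi2 * (V - Ei);
      k2Vi[c] = (iclamp[c] > 0) ? 0.0
        : (Ii[n + 1] + gN * etaI[c] - ipar[1] * (V - ipar[2]) - Isyn) / ipar[0];
      k2Si[c] = hsyn(V) * (1.0 - Sip[c]) / tri - Sip[c] / tdi;
    }

    // update + spike mechanics
    for (int c = 0; c < Ne; ++c) {
      for (int j = 0; j < nse; ++j) ye[c][j] += 0.5 * dt * (k1e[c][j] + k2e[c][j]);
      for (int j = 1; j < nse; ++j) {
        if (ye[c][j] < 0.0) ye[c][j] = 0.0; else if (ye[c][j] > 1.0) ye[c][j] = 1.0;
      }
      Se[c] += 0.5 * dt * (k1Se[c] + k2Se[c]);
      if (eclamp[c] > 0) {
        if (--eclamp[c] == 0) ye[c][0] = eVreset;
      } else {
        check_finite(ye[c][0], "E", c + 1);
        if (n >= arm_after && ye[c][0] > eVth) {
          spikes[c].push_back((n + 1) * dt);
          ye[c][0] = eVpeak;
          eclamp[c] = enclamp;
        }
      }
    }
    for (int c = 0; c < Ni; ++c) {
      Vi[c] += 0.5 * dt * (k1Vi[c] + k2Vi[c]);
      Si[c] += 0.5 * dt * (k1Si[c] + k2Si[c]);
      if (iclamp[c] > 0) {
        if (--iclamp[c] == 0) Vi[c] = iVreset;
      } else {
        check_finite(Vi[c], "I", c + 1);
        if (n >= arm_after && Vi[c] > iVth) {
          spikes[Ne + c].push_back((n + 1) * dt);
          Vi[c] = iVpeak;
          iclamp[c] = inclamp;
        }
      }
    }

    for (auto &kv : vrec) {
      int c = kv.first;
      kv.second[n + 1] = (c <= Ne) ? ye[c - 1][0] : Vi[c - Ne - 1];
    }
  }

  List sp(Ne + Ni);
  for (int c = 0; c < Ne + Ni; ++c)
    sp[c] = NumericVector(spikes[c].begin(), spikes[c].end());
  List out = List::create(_["spikes"] = sp);
  if (!vrec.empty()) {
    List vl;
    for (auto &kv : vrec) vl[std::string("cell") + std::to_string(kv.first)] = kv.second;
    out["V"] = vl;
  }
  return out;
}

// ------------------------------------- 3-layer feedforward (divergent) -----
// Layer 1: presynaptic voltage trace (point-process source). Layer 2: N2
// identical LIF cells with a shared plastic synaptic gate (same presynaptic
// neuron -> same S, D, F dynamics), independent noise. Layer 3: one LIF
// receiving one plain AMPA gate per layer-2 cell.

// [[Rcpp::export(name = ".sim_layers_cpp")]]
List sim_layers_cpp(NumericVector Vpre1, NumericVector ppar, NumericVector l2spike,
                    NumericVector I2, double sig2, int N2,
                    NumericVector l3par, NumericVector l3spike, NumericVector I3,
                    double g23, double tre, double tde, double Ee,
                    double gN, double dt, double master_seed, double trial_id,
                    bool record_v3, IntegerVector record_l2, int arm_after,
                    double v20, double v30) {
  const int nsteps = Vpre1.size() - 1;
  if (I2.size() != Vpre1.size() || I3.size() != Vpre1.size())
    stop("stimulus grids differ");
  // ppar layout is the plastic_lif layout (model 4)
  const double Vth2 = l2spike[0], Vreset2 = l2spike[1], Vpeak2 = l2spike[2];
  const double Vth3 = l3spike[0], Vreset3 = l3spike[1], Vpeak3 = l3spike[2];
  int nclamp2 = std::max(1, (int)std::lround(l2spike[3] / dt));
  int nclamp3 = std::max(1, (int)std::lround(l3spike[3] / dt));

  bool use_dep = ppar[11] != 0.0, use_fac = ppar[12] != 0.0;
  double S1 = 0.0, D1 = 1.0, F1 = use_fac ? 0.0 : 1.0;
  double Rel1 = (use_dep ? D1 : 1.0) * (use_fac ? F1 : 1.0);
  std::vector<double> V2(N2, v20), S2(N2, 0.0);
  std::vector<int> clamp2(N2, 0);
  double V3 = v30;
  int clamp3 = 0;

  std::vector<GaussRNG> rng(N2);
  for (int c = 0; c < N2; ++c)
    rng[c].seed3((uint64_t)master_seed, (uint64_t)(c + 1), (uint64_t)trial_id);

  std::vector<std::vector<double>> spikes(N2 + 1);
  NumericVector V3rec;
  if (record_v3) { V3rec = NumericVector(nsteps + 1); V3rec[0] = V3; }
  std::map<int, NumericVector> vrec2;
  for (int k = 0; k < record_l2.size(); ++k) {
    vrec2[record_l2[k]] = NumericVector(nsteps + 1);
    vrec2[record_l2[k]][0] = V2[record_l2[k] - 1];
  }

  std::vector<double> eta(N2), k1V(N2), k2V(N2), Vp(N2), k1S(N2), k2S(N2), Sp(N2);

  for (int n = 0; n < nsteps; ++n) {
    for (int c = 0; c < N2; ++c) eta[c] = (sig2 > 0) ? sig2 * rng[c].norm() : 0.0;
    double hv1 = hsyn(Vpre1[n]), hv1b = hsyn(Vpre1[n + 1]);
    if ((Vpre1[n + 1] > 0.0 && Vpre1[n] <= 0.0) || (n == 0 && Vpre1[0] > 0.0))
      Rel1 = (use_dep ? D1 : 1.0) * (use_fac ? F1 : 1.0);

    // stage 1
    double k1S1 = hv1 * (1.0 - S1) / ppar[5] - S1 / ppar[6];
    double k1D1 = use_dep ? (-hv1 * D1 / ppar[7] + (1.0 - D1) / ppar[8]) : 0.0;
    double k1F1 = use_fac ? (hv1 * (1.0 - F1) / ppar[9] - F1 / ppar[10]) : 0.0;
    double gate1 = S1 * Rel1;
    double sumS2 = 0.0;
    for (int c = 0; c < N2; ++c) sumS2 += S2[c];
    for (int c = 0; c < N2; ++c) {
      double V = V2[c];
      k1V[c] = (clamp2[c] > 0) ? 0.0
        : (I2[n] + gN * eta[c] - ppar[1] * (V - ppar[2])
           - ppar[3] * gate1 * (V - ppar[4])) / ppar[0];
      k1S[c] = hsyn(V) * (1.0 - S2[c]) / tre - S2[c] / tde;
      Vp[c] = V + dt * k1V[c];
      Sp[c] = S2[c] + dt * k1S[c];
    }
    double k1V3 = (clamp3 > 0) ? 0.0
      : (I3[n] - l3par[1] * (V3 - l3par[2]) - g23 * sumS2 * (V3 - Ee)) / l3par[0];

    // predictors for the shared gate
    double S1p = S1 + dt * k1S1, D1p = D1 + dt * k1D1, F1p = F1 + dt * k1F1;
    double V3p = V3 + dt * k1V3;

    // stage 2
    double k2S1 = hv1b * (1.0 - S1p) / ppar[5] - S1p / ppar[6];
    double k2D1 = use_dep ? (-hv1b * D1p / ppar[7] + (1.0 - D1p) / ppar[8]) : 0.0;
    double k2F1 = use_fac ? (hv1b * (1.0 - F1p) / ppar[9] - F1p / ppar[10]) : 0.0;
    double gate1p = S1p * Rel1;
    double sumS2p = 0.0;
    for (int c = 0; c < N2; ++c) sumS2p += Sp[c];
    for (int c = 0; c < N2; ++c) {
      double V = Vp[c];
      k2V[c] = (clamp2[c] > 0) ? 0.0
        : (I2[n + 1] + gN * eta[c] - ppar[1] * (V - ppar[2])
           - ppar[3] * gate1p * (V - ppar[4])) / ppar[0];
      k2S[c] = hsyn(V) * (1.0 - Sp[c]) / tre - Sp[c] / tde;
    }
    double k2V3 = (clamp3 > 0) ? 0.0
      : (I3[n + 1] - l3par[1] * (V3p - l3par[2]) - g23 * sumS2p * (V3p - Ee)) / l3par[0];

    // update
    S1 += 0.5 * dt * (k1S1 + k2S1);
    D1 += 0.5 * dt * (k1D1 + k2D1);
    F1 += 0.5 * dt * (k1F1 + k2F1);
    for (int c = 0; c < N2; ++c) {
      V2[c] += 0.5 * dt * (k1V[c] + k2V[c]);
      S2[c] += 0.5 * dt * (k1S[c] + k2S[c]);
      if (clamp2[c] > 0) {
        if (--clamp2[c] == 0) V2[c] = Vreset2;
      } else {
        check_finite(V2[c], "layer2", c + 1);
        if (n >= arm_after && V2[c] > Vth2) {
          spikes[c].push_back((n + 1) * dt);
          V2[c] = Vpeak2;
          clamp2[c] = nclamp2;
        }
      }
    }
    V3 += 0.5 * dt * (k1V3 + k2V3);
    if (clamp3 > 0) {
      if (--clamp3 == 0) V3 = Vreset3;
    } else {
      check_finite(V3, "layer3", 1);
      if (n >= arm_after && V3 > Vth3) {
        spikes[N2].push_back((n + 1) * dt);
        V3 = Vpeak3;
        clamp3 = nclamp3;
      }
    }

    if (record_v3) V3rec[n + 1] = V3;
    for (auto &kv : vrec2) kv.second[n + 1] = V2[kv.first - 1];
  }

  List sp(N2 + 1);
  for (int c = 0; c <= N2; ++c)
    sp[c] = NumericVector(spikes[c].begin(), spikes[c].end());
  List out = List::create(_["spikes"] = sp);
  if (record_v3) out["V3"] = V3rec;
  if (!vrec2.empty()) {
    List vl;
    for (auto &kv : vrec2) vl[std::string("cell") + std::to_string(kv.first)] = kv.second;
    out["V2"] = vl;
  }
  return out;
}

// -------------------------------------------- INT -> PYR two-cell motif ----
// One Wang-Buzsaki interneuron (with or without the M-like current) coupled
// to one 4D pyramidal cell through a GABA_A gate; optional reverse AMPA and
// self connections via the class conductances.

// [[Rcpp::export(name = ".sim_intpyr_cpp")]]
List sim_intpyr_cpp(NumericVector ipar, NumericVector epar,
                    NumericVector syn, // gee,gei,gie,gii,Ee,Ei,tre,tde,tri,tdi
                    NumericVector Ii, NumericVector Ie,
                    double sig_i, double sig_e, double gN,
                    double dt, double master_seed, double trial_id,
                    bool record, NumericVector yi0, NumericVector ye0) {
  const int nsteps = Ii.size() - 1;
  if (Ie.size() != Ii.size()) stop("stimulus grids differ");
  const double gee = syn[0], gei = syn[1], gie = syn[2], gii = syn[3];
  const double Ee = syn[4], Ei = syn[5];
  const double tre = syn[6], tde = syn[7], tri = syn[8], tdi = syn[9];

  double yi[4], ye4[4];
  for (int j = 0; j < 4; ++j) { yi[j] = yi0[j]; ye4[j] = ye0[j]; }
  double Si = 0.0, Sepre = 0.0; // gates keyed to INT and PYR respectively

  GaussRNG rngi, rnge;
  rngi.seed3((uint64_t)master_seed, 1, (uint64_t)trial_id);
  rnge.seed3((uint64_t)master_seed, 2, (uint64_t)trial_id);

  std::vector<double> spk_i, spk_e;
  NumericVector Virec, Verec;
  if (record) {
    Virec = NumericVector(nsteps + 1); Verec = NumericVector(nsteps + 1);
    Virec[0] = yi[0]; Verec[0] = ye4[0];
  }

  double k1i[4], k2i[4], yip[4], k1e[4], k2e[4], yep[4];

  for (int n = 0; n < nsteps; ++n) {
    double etai = (sig_i > 0) ? sig_i * rngi.norm() : 0.0;
    double etae = (sig_e > 0) ? sig_e * rnge.norm() : 0.0;

    // stage 1
    double IsynI = gie * Sepre * (yi[0] - Ee) + gii * Si * (yi[0] - Ei);
    double IsynE = gee * Sepre * (ye4[0] - Ee) + gei * Si * (ye4[0] - Ei);
    model_rhs(6, REAL(ipar), yi, Ii[n] + gN * etai, -60.0, IsynI, k1i);
    model_rhs(5, REAL(epar), ye4, Ie[n] + gN * etae, -60.0, IsynE, k1e);
    double k1Si = hsyn(yi[0]) * (1.0 - Si) / tri - Si / tdi;
    double k1Se = hsyn(ye4[0]) * (1.0 - Sepre) / tre - Sepre / tde;
    for (int j = 0; j < 4; ++j) { yip[j] = yi[j] + dt * k1i[j]; yep[j] = ye4[j] + dt * k1e[j]; }
    double Sip = Si + dt * k1Si, Sep = Sepre + dt * k1Se;

    // stage 2
    double IsynI2 = gie * Sep * (yip[0] - Ee) + gii * Sip * (yip[0] - Ei);
    double IsynE2 = gee * Sep * (yep[0] - Ee) + gei * Sip * (yep[0] - Ei);
    model_rhs(6, REAL(ipar), yip, Ii[n + 1] + gN * etai, -60.0, IsynI2, k2i);
    model_rhs(5, REAL(epar), yep, Ie[n + 1] + gN * etae, -60.0, IsynE2, k2e);
    double k2Si = hsyn(yip[0]) * (1.0 - Sip) / tri - Sip / tdi;
    double k2Se = hsyn(yep[0]) * (1.0 - Sep) / tre - Sep / tde;

    double Vi_old = yi[0], Ve_old = ye4[0];
    for (int j = 0; j < 4; ++j) {
      yi[j] += 0.5 * dt * (k1i[j] + k2i[j]);
      ye4[j] += 0.5 * dt * (k1e[j] + k2e[j]);
      if (j > 0) {
        if (yi[j] < 0.0) yi[j] = 0.0; else if (yi[j] > 1.0) yi[j] = 1.0;
        if (ye4[j] < 0.0) ye4[j] = 0.0; else if (ye4[j] > 1.0) ye4[j] = 1.0;
      }
    }
    Si += 0.5 * dt * (k1Si + k2Si);
    Sepre += 0.5 * dt * (k1Se + k2Se);
    check_finite(yi[0], "INT", 1);
    check_finite(ye4[0], "PYR", 2);
    if (Vi_old < 0.0 && yi[0] >= 0.0) spk_i.push_back((n + 1) * dt);
    if (Ve_old < 0.0 && ye4[0] >= 0.0) spk_e.push_back((n + 1) * dt);

    if (record) { Virec[n + 1] = yi[0]; Verec[n + 1] = ye4[0]; }
  }

  List out = List::create(
    _["spikes_int"] = NumericVector(spk_i.begin(), spk_i.end()),
    _["spikes_pyr"] = NumericVector(spk_e.begin(), spk_e.end()));
  if (record) { out["V_int"] = Virec; out["V_pyr"] = Verec; }
  return out;
}
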