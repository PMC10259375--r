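// Mahajan et al. (2008) rabbit ventricular action potential model,
// transcribed from the published formulation (LR-type INa, Markov ICaL,
// IKr, IKs, Ito fast/slow, IK1, NCX, NaK pump, Shiferaw-style Ca cycling),
// plus forward-Euler integration of the myocyte coupled to N passive
// fibroblasts through ohmic gap junctions.
//
// Units: time ms, voltage mV, membrane currents uA/uF (= pA/pF),
// gap/fibroblast currents pA, Ca in uM (nai in mM), conductances mS/uF,
// g_gap nS, capacitances pF.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 26;

// state indices
enum {
  iV = 0, ixm, ixh, ixj, ixr, ixs1, ixs2, ixtos, iytos, ixtof, iytof,
  ic1, ic2, ixi1ca, ixi1ba, ixi2ca, ixi2ba,
  icp, ics, ici, icj, icjp, ixir, itropi, itrops, inai
};

static const char *STATE_NAMES[NSTATE] = {
  "Vm", "xm", "xh", "xj", "xr", "xs1", "xs2", "xtos", "ytos", "xtof", "ytof",
  "c1", "c2", "xi1ca", "xi1ba", "xi2ca", "xi2ba",
  "cp", "cs", "ci", "cj", "cjp", "xir", "tropi", "trops", "nai"
};

// fixed ionic conditions and physical constants
static const double xnao = 136.0;   // mM
static const double xki  = 140.0;   // mM
static const double xko  = 5.4;     // mM
static const double cao  = 1.8;     // mM
static const double FRT  = 96485.0 / (8314.472 * 308.0); // 1/mV at 308 K
static const double wca  = 8.0313;  // uA/uF per uM/ms (Cm 3.1e-4 uF, vi 2.58e-5 uL)

struct MyoParams {
  double gna;    // mS/uF (nominal * scale)
  double gk1;    // mS/uF (nominal * scale)
  double gkr, gks, gtos, gtof, gnak, gnaca;
  double pca;    // cm/s
  double gca;    // Ca flux strength, mmol/(cm C)
};

struct Currents {
  double ina, ical, ikr, iks, itof, itos, ik1, inaca, inak, itotal;
};

// Full right-hand side. deriv must have length NSTATE.
static void mahajan_rhs(const double *y, const MyoParams &p, double iext,
                        double *deriv, Currents &cur) {
  const double v = y[iV];
  const double nai = y[inai];
  const double cs = y[ics], ci = y[ici], cp = y[icp];
  const double cj = y[icj], cjp = y[icjp];

  const double ek = (1.0 / FRT) * std::log(xko / xki);
  const double ena = (1.0 / FRT) * std::log(xnao / nai);

  // ---- INa (Luo-Rudy kinetics) ----
  double am = (std::fabs(v + 47.13) < 1e-6)
    ? 3.2
    : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
  double bm = 0.08 * std::exp(-v / 11.0);
  double ah, bh, aj, bj;
  if (v < -40.0) {
    ah = 0.135 * std::exp(-(80.0 + v) / 6.8);
    bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
    aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  }
  cur.ina = p.gna * y[ixh] * y[ixj] * y[ixm] * y[ixm] * y[ixm] * (v - ena);
  deriv[ixm] = am * (1.0 - y[ixm]) - bm * y[ixm];
  deriv[ixh] = ah * (1.0 - y[ixh]) - bh * y[ixh];
  deriv[ixj] = aj * (1.0 - y[ixj]) - bj * y[ixj];

  // ---- ICaL: 7-state Markov gating, GHK driving term ----
  const double csm = cs / 1000.0; // uM -> mM
  const double za = v * 2.0 * FRT;
  // rxa in mA/cm^2-scale literal units; membrane current is 1000*rxa*po
  const double factor1 = 4.0 * p.pca * 96.485 * FRT;
  double rxa;
  if (std::fabs(za) < 1e-3) {
    rxa = factor1 * (csm * std::exp(za) - 0.341 * cao) / (2.0 * FRT);
  } else {
    rxa = v * factor1 * (csm * std::exp(za) - 0.341 * cao) / (std::exp(za) - 1.0);
  }

  const double poinf = 1.0 / (1.0 + std::exp(-v / 8.0));       // vth 0, s6 8
  const double taupo = 1.0;
  const double alpha = poinf / taupo;
  const double beta = (1.0 - poinf) / taupo;
  const double r1 = 0.3, r2 = 3.0;
  const double cat = 3.0;
  const double fca = 1.0 / (1.0 + std::pow(cat / cp, 3.0));
  const double s1 = 0.0182688 * fca;
  const double s1t = 0.00195;
  const double xk1 = 0.024168 * fca;
  const double xk2 = 1.03615e-4;
  const double xk1t = 0.00413;
  const double xk2t = 0.00224;
  const double s2 = s1 * (r1 / r2) * (xk2 / xk1);
  const double s2t = s1t * (r1 / r2) * (xk2t / xk1t);
  const double poi = 1.0 / (1.0 + std::exp(-(v + 40.0) / 3.0)); // vx -40, sx 3
  const double tau3 = 3.0;
  const double xk3 = (1.0 - poi) / tau3;
  const double xk3t = xk3;
  const double prv = 1.0 - 1.0 / (1.0 + std::exp(-(v + 40.0) / 4.0)); // vy -40, sy 4
  const double recov = 10.0 + 4954.0 * std::exp(v / 15.6);
  const double tca = 78.0329;
  const double cpt = 6.09365;
  const double tau_ca = tca / (1.0 + std::pow(cp / cpt, 4.0)) + 0.1;
  const double tauca = (recov - tau_ca) * prv + tau_ca;
  const double tauba = (recov - 450.0) * prv + 450.0;
  const double ps = 1.0 / (1.0 + std::exp(-(v + 40.0) / 11.32)); // vyr -40, syr 11.32
  const double xk6 = fca * ps / tauca;
  const double xk5 = (1.0 - ps) / tauca;
  const double xk6t = ps / tauba;
  const double xk5t = (1.0 - ps) / tauba;
  const double xk4 = xk3 * (alpha / beta) * (xk1 / xk2) * (xk5 / xk6);
  const double xk4t = xk3t * (alpha / beta) * (xk1t / xk2t) * (xk5t / xk6t);

  const double c1 = y[ic1], c2 = y[ic2];
  const double xi1ca = y[ixi1ca], xi1ba = y[ixi1ba];
  const double xi2ca = y[ixi2ca], xi2ba = y[ixi2ba];
  const double po = 1.0 - xi1ca - xi2ca - xi1ba - xi2ba - c1 - c2;

  deriv[ic1] = alpha * c2 + xk2 * xi1ca + xk2t * xi1ba + r2 * po -
               (beta + r1 + xk1t + xk1) * c1;
  deriv[ic2] = beta * c1 + xk5 * xi2ca + xk5t * xi2ba - (xk6 + xk6t + alpha) * c2;
  deriv[ixi1ca] = xk1 * c1 + xk4 * xi2ca + s1 * po - (xk3 + xk2 + s2) * xi1ca;
  deriv[ixi2ca] = xk3 * xi1ca + xk6 * c2 - (xk5 + xk4) * xi2ca;
  deriv[ixi1ba] = xk1t * c1 + xk4t * xi2ba + s1t * po - (xk3t + xk2t + s2t) * xi1ba;
  deriv[ixi2ba] = xk3t * xi1ba + xk6t * c2 - (xk5t + xk4t) * xi2ba;

  // Ca flux through the L-type channel (uM/ms, current sign convention);
  // the membrane current is charge-consistent: valence 2 x wca x flux.
  const double jca = p.gca * po * rxa;
  cur.ical = 2.0 * wca * jca; // uA/uF

  // ---- IKr ----
  {
    const double gss = std::sqrt(xko / 5.4);
    double xkrv1 = (std::fabs(v + 7.0) < 1e-6)
      ? 0.00138 / 0.123
      : 0.00138 * (v + 7.0) / (1.0 - std::exp(-0.123 * (v + 7.0)));
    double xkrv2 = (std::fabs(v + 10.0) < 1e-6)
      ? 0.00061 / 0.145
      : 0.00061 * (v + 10.0) / (std::exp(0.145 * (v + 10.0)) - 1.0);
    const double taukr = 1.0 / (xkrv1 + xkrv2);
    const double xkrinf = 1.0 / (1.0 + std::exp(-(v + 50.0) / 7.5));
    const double rg = 1.0 / (1.0 + std::exp((v + 33.0) / 22.4));
    cur.ikr = p.gkr * gss * y[ixr] * rg * (v - ek);
    deriv[ixr] = (xkrinf - y[ixr]) / taukr;
  }

  // ---- IKs (Ca-sensitive conductance) ----
  {
    const double prnak = 0.018330;
    const double eks = (1.0 / FRT) *
      std::log((xko + prnak * xnao) / (xki + prnak * nai));
    const double xs1ss = 1.0 / (1.0 + std::exp(-(v - 1.5) / 16.7));
    double t1 = (std::fabs(v + 30.0) < 1e-6)
      ? 7.19e-5 / 0.148
      : 7.19e-5 * (v + 30.0) / (1.0 - std::exp(-0.148 * (v + 30.0)));
    double t2 = (std::fabs(v + 30.0) < 1e-6)
      ? 1.31e-4 / 0.0687
      : 1.31e-4 * (v + 30.0) / (std::exp(0.0687 * (v + 30.0)) - 1.0);
    const double tauxs1 = 1.0 / (t1 + t2);
    const double tauxs2 = 4.0 * tauxs1;
    const double gksx = 1.0 + 0.8 / (1.0 + std::pow(0.5 / ci, 3.0));
    cur.iks = p.gks * gksx * y[ixs1] * y[ixs2] * (v - eks);
    deriv[ixs1] = (xs1ss - y[ixs1]) / tauxs1;
    deriv[ixs2] = (xs1ss - y[ixs2]) / tauxs2;
  }

  // ---- Ito slow and fast ----
  {
    const double rt1 = -(v + 3.0) / 15.0;
    const double rt2 = (v + 33.5) / 10.0;
    const double rt3 = (v + 60.0) / 10.0;
    const double xtos_inf = 1.0 / (1.0 + std::exp(rt1));
    const double ytos_inf = 1.0 / (1.0 + std::exp(rt2));
    const double rs_inf = 1.0 / (1.0 + std::exp(rt2));
    const double txs = 9.0 / (1.0 + std::exp(-rt1)) + 0.5;
    const double tys = 3000.0 / (1.0 + std::exp(rt3)) + 30.0;
    cur.itos = p.gtos * y[ixtos] * (y[iytos] + 0.5 * rs_inf) * (v - ek);
    deriv[ixtos] = (xtos_inf - y[ixtos]) / txs;
    deriv[iytos] = (ytos_inf - y[iytos]) / tys;

    const double xtof_inf = xtos_inf;
    const double ytof_inf = ytos_inf;
    const double txf = 3.5 * std::exp(-(v / 30.0) * (v / 30.0)) + 1.5;
    const double tyf = 20.0 / (1.0 + std::exp(rt2)) + 20.0;
    cur.itof = p.gtof * y[ixtof] * y[iytof] * (v - ek);
    deriv[ixtof] = (xtof_inf - y[ixtof]) / txf;
    deriv[iytof] = (ytof_inf - y[iytof]) / tyf;
  }

  // ---- IK1 ----
  {
    const double aki = 1.02 / (1.0 + std::exp(0.2385 * (v - ek - 59.215)));
    const double bki = (0.49124 * std::exp(0.08032 * (v - ek + 5.476)) +
                        std::exp(0.06175 * (v - ek - 594.31))) /
                       (1.0 + std::exp(-0.5143 * (v - ek + 4.753)));
    const double xkin = aki / (aki + bki);
    cur.ik1 = p.gk1 * std::sqrt(xko / 5.4) * xkin * (v - ek);
  }

  // ---- INaK ----
  {
    const double xkmko = 1.5, xkmnai = 12.0;
    const double sigma = (std::exp(xnao / 67.3) - 1.0) / 7.0;
    const double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v * FRT) +
                               0.0365 * sigma * std::exp(-v * FRT));
    cur.inak = p.gnak * fnak * (1.0 / (1.0 + xkmnai / nai)) * xko / (xko + xkmko);
  }

  // ---- INaCa (flux in uM/ms; current = wca * flux) ----
  double xinacaq;
  {
    const double zw3 = std::pow(nai, 3.0) * cao * std::exp(v * 0.35 * FRT) -
                       std::pow(xnao, 3.0) * csm * std::exp(v * (0.35 - 1.0) * FRT);
    const double zw4 = 1.0 + 0.2 * std::exp(v * (0.35 - 1.0) * FRT);
    const double xkdna = 0.3; // uM
    const double aloss = 1.0 / (1.0 + std::pow(xkdna / cs, 3.0));
    const double xmcao = 1.3, xmnao = 87.5, xmnai = 12.3, xmcai = 0.0036;
    const double yz1 = xmcao * std::pow(nai, 3.0) + std::pow(xmnao, 3.0) * csm;
    const double yz2 = std::pow(xmnai, 3.0) * cao * (1.0 + csm / xmcai);
    const double yz3 = xmcai * std::pow(xnao, 3.0) *
                       (1.0 + std::pow(nai / xmnai, 3.0));
    const double yz4 = std::pow(nai, 3.0) * cao + std::pow(xnao, 3.0) * csm;
    const double zw8 = yz1 + yz2 + yz3 + yz4;
    xinacaq = p.gnaca * aloss * zw3 / (zw4 * zw8);
  }
  cur.inaca = wca * xinacaq;

  // ---- Ca cycling ----
  // jca (uM/ms, current sign: negative = influx) defined above with ICaL

  // SR release source Qr
  const double cstar = 90.0, av = 11.3;
  const double bv = (cstar - 50.0) - av * cstar;
  double qr0;
  if (cjp < 50.0) qr0 = 0.0;
  else if (cjp < cstar) qr0 = cjp - 50.0;
  else qr0 = av * cjp + bv;
  const double qr = cj * qr0 / cstar;

  // uptake, leak, diffusion
  const double vup = 0.4, cup = 0.5;
  const double jup = vup * ci * ci / (ci * ci + cup * cup);
  const double gleak = 2.069e-5, kj = 50.0;
  const double jleak = gleak * (cj * cj / (cj * cj + kj * kj)) * (cj * 16.667 - ci);
  const double taud = 4.0;
  const double jd = (cs - ci) / taud;

  // instantaneous buffering
  const double bcal = 24.0, xkcal = 7.0, srmax = 47.0, srkd = 0.6;
  const double bmem = 15.0, kmem = 0.3, bsar = 42.0, ksar = 13.0;
  const double bpxs = bcal * xkcal / ((xkcal + cs) * (xkcal + cs));
  const double spxs = srmax * srkd / ((srkd + cs) * (srkd + cs));
  const double mempxs = bmem * kmem / ((kmem + cs) * (kmem + cs));
  const double sarpxs = bsar * ksar / ((ksar + cs) * (ksar + cs));
  const double dcsib = 1.0 / (1.0 + bpxs + spxs + mempxs + sarpxs);
  const double bpxi = bcal * xkcal / ((xkcal + ci) * (xkcal + ci));
  const double spxi = srmax * srkd / ((srkd + ci) * (srkd + ci));
  const double mempxi = bmem * kmem / ((kmem + ci) * (kmem + ci));
  const double sarpxi = bsar * ksar / ((ksar + ci) * (ksar + ci));
  const double dciib = 1.0 / (1.0 + bpxi + spxi + mempxi + sarpxi);

  // troponin binding
  const double xkon = 0.0327, xkoff = 0.0196, btrop = 70.0;
  const double xbi = xkon * ci * (btrop - y[itropi]) - xkoff * y[itropi];
  const double xbs = xkon * cs * (btrop - y[itrops]) - xkoff * y[itrops];

  const double dcj = -y[ixir] + jup - jleak;

  // RyR release flux dynamics
  {
    const double ay = 0.05, gryr = 2.58079, taur = 32.5;
    const double sparkv = std::exp(-ay * (v + 30.0)) /
                          (1.0 + std::exp(-ay * (v + 30.0)));
    const double spark_rate = gryr * po * std::fabs(rxa) * sparkv;
    deriv[ixir] = spark_rate * qr - y[ixir] * (1.0 - taur * dcj / cj) / taur;
  }

  // dyadic junctional Ca
  {
    const double ax = 0.3576, gbarsr = 26841.8, gdyad = 9000.0, taups = 0.5;
    const double gate = std::exp(-ax * (v + 30.0)) /
                        (1.0 + std::exp(-ax * (v + 30.0)));
    const double xirp = po * qr * std::fabs(rxa) * gbarsr * gate;
    const double xicap = po * gdyad * std::fabs(rxa);
    deriv[icp] = xirp + xicap - (cp - cs) / taups;
  }

  deriv[ics] = dcsib * (50.0 * (y[ixir] - jd - jca + xinacaq) - xbs);
  deriv[ici] = dciib * (jd - jup + jleak - xbi);
  deriv[icj] = dcj;
  deriv[icjp] = (cj - cjp) / 100.0; // taua
  deriv[itropi] = xbi;
  deriv[itrops] = xbs;

  deriv[inai] = -(cur.ina + 3.0 * cur.inak + 3.0 * cur.inaca) / (wca * 1000.0);

  cur.itotal = cur.ina + cur.ical + cur.ikr + cur.iks + cur.itof + cur.itos +
               cur.ik1 + cur.inaca + cur.inak;
  deriv[iV] = -cur.itotal + iext;
}

static MyoParams params_from_list(const List &par) {
  MyoParams p;
  p.gna = as<double>(par["gNa_nominal"]) * as<double>(par["gNa_scale"]);
  p.gk1 = as<double>(par["gK1_nominal"]) * as<double>(par["gK1_scale"]);
  p.gkr = as<double>(par["gKr"]);
  p.gks = as<double>(par["gKs"]);
  p.gtos = as<double>(par["gtos"]);
  p.gtof = as<double>(par["gtof"]);
  p.gnak = as<double>(par["gNaK"]);
  p.gnaca = as<double>(par["gNaCa"]);
  p.pca = as<double>(par["pCa"]);
  p.gca = as<double>(par["gCaFlux"]);
  return p;
}

static void check_state(const NumericVector &state) {
  if (state.size() != NSTATE)
    stop("myocyte state must have %d entries, got %d", NSTATE, (int)state.size());
  for (int i = 0; i < NSTATE; ++i) {
    if (!R_finite(state[i]))
      stop("invalid myocyte state: variable '%s' is non-finite", STATE_NAMES[i]);
  }
}

// [[Rcpp::export(name = ".mahajan_rhs_cpp")]]
List mahajan_rhs_cpp(NumericVector state, List params, double i_ext) {
  check_state(state);
  if (!R_finite(i_ext)) stop("I_ext must be finite");
  MyoParams p = params_from_list(params);
  std::vector<double> deriv(NSTATE);
  Currents cur;
  mahajan_rhs(&state[0], p, i_ext, deriv.data(), cur);
  NumericVector d(deriv.begin(), deriv.end());
  d.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
  NumericVector cb = NumericVector::create(
    _["I_Na"] = cur.ina, _["I_CaL"] = cur.ical, _["I_Kr"] = cur.ikr,
    _["I_Ks"] = cur.iks, _["I_to_f"] = cur.itof, _["I_to_s"] = cur.itos,
    _["I_K1"] = cur.ik1, _["I_NaCa"] = cur.inaca, _["I_NaK"] = cur.inak,
    _["I_ion"] = cur.itotal);
  return List::create(_["deriv"] = d, _["currents"] = cb);
}

// Passive fibroblast: I_f(pA) = amp * (A/(1+exp((vh - V)/k)) + C).
// amp, A, vh, k, C are pre-resolved in R so that I_f(E_rev) = 0.
struct FibSpec {
  double amp, A, vh, k, C, cm; // cm in pF
};

static inline double fib_current(double vf, const FibSpec &f) {
  return f.amp * (f.A / (1.0 + std::exp((f.vh - vf) / f.k)) + f.C);
}

// Integrate the coupled myocyte + N fibroblast system with adaptive
// forward Euler (per-step dt = clamp(theta/max|dV/dt|, dt_min, dt_max)).
//
// stim_times: onsets (ms) of rectangular stimuli of stim_dur ms and
// stim_amp uA/uF. Recording on a uniform grid of record_dt ms.
// [[Rcpp::export(name = ".integrate_coupled_cpp")]]
List integrate_coupled_cpp(NumericVector state0, NumericVector vf0,
                           List params, double cm_myo,
                           NumericVector g_gap, List fib_specs,
                           NumericVector stim_times, double stim_dur,
                           double stim_amp, double t_end,
                           double dt_min, double dt_max, double theta,
                           double record_dt) {
  check_state(state0);
  MyoParams p = params_from_list(params);
  const int nf = vf0.size();
  if ((int)g_gap.size() != nf) stop("g_gap must have one entry per fibroblast");
  if ((int)fib_specs.size() != nf) stop("fib_specs must have one entry per fibroblast");
  if (dt_min <= 0 || dt_max < dt_min) stop("need 0 < dt_min <= dt_max");
  if (cm_myo <= 0) stop("Cm_myo must be positive");

  std::vector<FibSpec> fibs(nf);
  for (int i = 0; i < nf; ++i) {
    List fs = fib_specs[i];
    fibs[i].amp = as<double>(fs["amp"]);
    fibs[i].A = as<double>(fs["A"]);
    fibs[i].vh = as<double>(fs["vh"]);
    fibs[i].k = as<double>(fs["k"]);
    fibs[i].C = as<double>(fs["C"]);
    fibs[i].cm = as<double>(fs["cm"]);
    if (fibs[i].cm <= 0) stop("fibroblast capacitance must be positive");
  }

  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];
  std::vector<double> vf(vf0.begin(), vf0.end());

  const int nrec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector rec_t(nrec), rec_vm(nrec), rec_ical(nrec), rec_stim(nrec);
  NumericMatrix rec_vf(nrec, nf), rec_igap(nrec, nf);

  double deriv[NSTATE];
  Currents cur;
  std::vector<double> igap(nf), dvf(nf);

  double t = 0.0;
  int irec = 0;
  const int nstim = stim_times.size();
  int next_stim = 0;

  // record helper (records state at current t for grid slot irec)
  auto record = [&](double istim_now) {
    rec_t[irec] = irec * record_dt;
    rec_vm[irec] = y[iV];
    rec_ical[irec] = cur.ical;
    rec_stim[irec] = istim_now;
    for (int i = 0; i < nf; ++i) {
      rec_vf(irec, i) = vf[i];
      rec_igap(irec, i) = igap[i];
    }
    ++irec;
  };

  // currents at t = 0 for the first record
  {
    double istim = 0.0;
    for (int s = 0; s < nstim; ++s)
      if (t >= stim_times[s] && t < stim_times[s] + stim_dur) istim = stim_amp;
    double igap_tot = 0.0;
    for (int i = 0; i < nf; ++i) {
      igap[i] = g_gap[i] * (y[iV] - vf[i]);
      igap_tot += igap[i];
    }
    mahajan_rhs(y, p, istim - igap_tot / cm_myo, deriv, cur);
    record(istim);
  }

  while (t < t_end - 1e-12) {
    // stimulus at current time
    double istim = 0.0;
    while (next_stim < nstim && t >= stim_times[next_stim] + stim_dur) ++next_stim;
    for (int s = next_stim; s < nstim; ++s) {
      if (t >= stim_times[s] && t < stim_times[s] + stim_dur) { istim = stim_amp; break; }
      if (stim_times[s] > t) break;
    }

    // gap currents (pA); positive = leaving the myocyte
    double igap_tot = 0.0;
    for (int i = 0; i < nf; ++i) {
      igap[i] = g_gap[i] * (y[iV] - vf[i]);
      igap_tot += igap[i];
    }

    mahajan_rhs(y, p, istim - igap_tot / cm_myo, deriv, cur);
    double maxdv = std::fabs(deriv[iV]);
    for (int i = 0; i < nf; ++i) {
      dvf[i] = (-fib_current(vf[i], fibs[i]) + igap[i]) / fibs[i].cm;
      if (std::fabs(dvf[i]) > maxdv) maxdv = std::fabs(dvf[i]);
    }

    double dt = (maxdv > 0) ? theta / maxdv : dt_max;
    if (dt < dt_min) dt = dt_min;
    if (dt > dt_max) dt = dt_max;
    // do not step across a stimulus onset
    if (next_stim < nstim && t < stim_times[next_stim] &&
        t + dt > stim_times[next_stim])
      dt = stim_times[next_stim] - t;
    if (t + dt > t_end) dt = t_end - t;

    for (int i = 0; i < NSTATE; ++i) y[i] += dt * deriv[i];
    for (int i = 0; i < nf; ++i) vf[i] += dt * dvf[i];
    t += dt;

    if (!R_finite(y[iV]) || y[iV] < -120.0 || y[iV] > 80.0)
      stop("aborted run: Vm = %g mV outside [-120, 80] at t = %g ms", y[iV], t);

    // record any grid points reached
    while (irec < nrec && t >= irec * record_dt - 1e-9) {
      double istim_now = 0.0;
      for (int s = 0; s < nstim; ++s)
        if (t >= stim_times[s] && t < stim_times[s] + stim_dur) istim_now = stim_amp;
      for (int i = 0; i < nf; ++i) igap[i] = g_gap[i] * (y[iV] - vf[i]);
      mahajan_rhs(y, p, 0.0, deriv, cur); // refresh currents for recording
      record(istim_now);
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector final_state(y, y + NSTATE);
  final_state.attr("names") = CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
  return List::create(
    _["time"] = rec_t, _["Vm"] = rec_vm, _["Vf"] = rec_vf,
    _["I_CaL"] = rec_ical, _["I_gap"] = rec_igap, _["stim"] = rec_stim,
    _["state_final"] = final_state,
    _["vf_final"] = NumericVector(vf.begin(), vf.end()));
}
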