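// Compiled inner loop for the dual-timescale homeostatic burster.
//
// Gate kinetics are the canonical seven-conductance crustacean STG
// formulation (Na m3h, CaT m3h, CaS m3h, A m3h, KCa m4, Kd m4, H m) with
// half-(in)activation baselines equal to the package's channel table; only
// the half-voltages are shiftable, slopes and time constants are fixed.
//
// Integration: exponential Euler for gates, forward Euler for V and Ca.
// Units: mV, ms, nA, uS, nF, uM throughout the loop; regulation time
// constants are passed in seconds and converted once.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NG = 11;   // gates: mNa hNa mCaT hCaT mCaS hCaS mA hA mKCa mKd mH
static const int NC = 7;    // channels: Na CaT CaS A KCa Kd H

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(x)); }

// steady-state of gate g at (already shift-corrected) voltage v;
// the KCa calcium factor is applied by the caller.
static double gate_inf_base(int g, double v) {
  switch (g) {
  case 0:  return sigm(-(v + 25.5) / 5.29);   // mNa
  case 1:  return sigm( (v + 48.9) / 5.18);   // hNa
  case 2:  return sigm(-(v + 27.1) / 7.2);    // mCaT
  case 3:  return sigm( (v + 32.1) / 5.5);    // hCaT
  case 4:  return sigm(-(v + 33.0) / 8.1);    // mCaS
  case 5:  return sigm( (v + 60.0) / 6.2);    // hCaS
  case 6:  return sigm(-(v + 27.2) / 8.7);    // mA
  case 7:  return sigm( (v + 56.9) / 4.9);    // hA
  case 8:  return sigm(-(v + 28.3) / 12.6);   // mKCa (voltage part)
  case 9:  return sigm(-(v + 12.3) / 11.8);   // mKd
  default: return sigm( (v + 70.0) / 6.0);    // mH (hyperpolarization-activated)
  }
}

// gate time constant (ms) at voltage v; never shifted
static double gate_tau(int g, double v) {
  switch (g) {
  case 0:  return 1.32 - 1.26 * sigm(-(v + 120.0) / 25.0);
  case 1:  return (0.67 * sigm(-(v + 62.9) / 10.0)) * (1.5 + sigm((v + 34.9) / 3.6));
  case 2:  return 21.7 - 21.3 * sigm(-(v + 68.1) / 20.5);
  case 3:  return 105.0 - 89.8 * sigm(-(v + 55.0) / 16.9);
  case 4:  return 1.4 + 7.0 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 70.0) / 13.0));
  case 5:  return 60.0 + 150.0 / (std::exp((v + 55.0) / 9.0) + std::exp(-(v + 65.0) / 16.0));
  case 6:  return 11.6 - 10.4 * sigm(-(v + 32.9) / 15.2);
  case 7:  return 38.6 - 29.2 * sigm(-(v + 38.9) / 26.5);
  case 8:  return 90.3 - 75.1 * sigm(-(v + 46.0) / 22.7);
  case 9:  return 7.2 - 6.4 * sigm(-(v + 28.3) / 19.2);
  default: return 272.0 + 1499.0 * sigm(-(v + 42.2) / 8.73);
  }
}

// [[Rcpp::export]]
double gate_inf_cpp(int g, double v) { return gate_inf_base(g, v); }

// [[Rcpp::export]]
double gate_tau_cpp(int g, double v) { return gate_tau(g, v); }

// piecewise-linear lookup table on a fixed voltage grid
struct Table {
  double x0, inv_dx;
  std::vector<double> y;
  double at(double x) const {
    double u = (x - x0) * inv_dx;
    if (!(u > 0.0)) return y.front();  // also catches NaN voltages

    size_t n = y.size() - 1;
    if (u >= (double)n) return y.back();
    size_t i = (size_t)u;
    double f = u - (double)i;
    return y[i] + f * (y[i + 1] - y[i]);
  }
};

static void build_tables(double dt, std::vector<Table>& inf_tab, std::vector<Table>& edt_tab) {
  const double x0 = -200.0, x1 = 150.0, dx = 0.02;
  size_t n = (size_t)((x1 - x0) / dx) + 1;
  inf_tab.resize(NG); edt_tab.resize(NG);
  for (int g = 0; g < NG; g++) {
    inf_tab[g].x0 = x0; inf_tab[g].inv_dx = 1.0 / dx; inf_tab[g].y.resize(n);
    edt_tab[g].x0 = x0; edt_tab[g].inv_dx = 1.0 / dx; edt_tab[g].y.resize(n);
    for (size_t i = 0; i < n; i++) {
      double v = x0 + dx * (double)i;
      inf_tab[g].y[i] = gate_inf_base(g, v);
      edt_tab[g].y[i] = std::exp(-dt / gate_tau(g, v));
    }
  }
}

// [[Rcpp::export]]
List simulate_core(double v0, NumericVector gates0, double ca_init,
                   NumericVector filters0,
                   NumericVector gmax0, double gleak,
                   NumericVector shifts0,
                   NumericMatrix schedule,   // cols: start_s dur_s E_K E_leak
                   List reg, List consts,
                   double dt, double v_rec_ms, double p_rec_ms,
                   bool record_v, bool use_tables) {
  if (gates0.size() != NG) stop("need %d gate values", NG);
  if (gmax0.size() != NC) stop("need %d conductances", NC);
  if (shifts0.size() != NG) stop("need %d half-shifts", NG);
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms");

  // constants
  const double C        = as<double>(consts["C_nF"]);
  const double tauCa    = as<double>(consts["tau_ca_ms"]);
  const double fCa      = as<double>(consts["f_ca"]);      // uM/nA
  const double Ca0      = as<double>(consts["ca_rest"]);   // uM
  const double caExt    = as<double>(consts["ca_ext_uM"]);
  const double nernstCa = as<double>(consts["nernst_ca_mV"]); // RT/2F in mV
  const double ENa      = as<double>(consts["E_Na"]);
  const double EH       = as<double>(consts["E_H"]);
  const double KhalfCa  = as<double>(consts["kca_half_uM"]);
  const double thresh   = as<double>(consts["spike_threshold_mV"]);
  const double refr     = as<double>(consts["spike_min_sep_ms"]);
  const double tauF     = as<double>(consts["tau_fast_ms"]);
  const double tauS     = as<double>(consts["tau_slow_ms"]);
  const double tauD     = as<double>(consts["tau_dc_ms"]);
  const double tauAvg   = as<double>(consts["tau_avg_ms"]);

  // regulation
  const double tau_g    = as<double>(reg["tau_g"]);     // s, may be Inf
  const double tau_half = as<double>(reg["tau_half"]);  // s, may be Inf
  const bool   en_g     = as<bool>(reg["enable_g"]) && R_finite(tau_g);
  const bool   en_h     = as<bool>(reg["enable_half"]) && R_finite(tau_half);
  const double lambda   = as<double>(reg["lambda"]);    // 1/s
  NumericMatrix Wg = reg["w_g"];      // 7 x 3
  NumericMatrix Wh = reg["w_half"];   // 11 x 3 (entries carry gain, mV)
  NumericVector targets = reg["targets"]; // uM; F, S, D
  const double deadzone = as<double>(reg["error_deadzone"]);
  NumericVector anchor = reg["shift_anchor"]; // mV; structural offsets
  const bool regulate = en_g || en_h;

  const double dts = dt * 1e-3; // s

  // filter relaxation coefficients (exact for constant input over dt)
  const double aF = 1.0 - std::exp(-dt / tauF);
  const double aS = 1.0 - std::exp(-dt / tauS);
  const double aD = 1.0 - std::exp(-dt / tauD);
  const double aA = 1.0 - std::exp(-dt / tauAvg);

  // schedule -> per-epoch env; times in ms
  int n_ep = schedule.nrow();
  std::vector<double> ep_end(n_ep);
  double total_ms = 0.0;
  for (int i = 0; i < n_ep; i++) {
    total_ms += schedule(i, 1) * 1000.0;
    ep_end[i] = total_ms;
  }

  std::vector<Table> inf_tab, edt_tab;
  if (use_tables) build_tables(dt, inf_tab, edt_tab);

  // state
  double V = v0, Ca = ca_init;
  double gates[NG], g[NC], sh[NG];
  for (int i = 0; i < NG; i++) gates[i] = gates0[i];
  for (int i = 0; i < NC; i++) g[i] = gmax0[i];
  for (int i = 0; i < NG; i++) sh[i] = shifts0[i];
  double cF = filters0[0], cS = filters0[1], cD = filters0[2];
  double aFst = filters0[3], aSlw = filters0[4];

  long n_steps = (long)std::llround(total_ms / dt);
  long v_every = record_v ? (long)std::llround(v_rec_ms / dt) : 0;
  long p_every = (long)std::llround(p_rec_ms / dt);
  if (p_every < 1) p_every = 1;
  if (record_v && v_every < 1) v_every = 1;

  std::vector<double> t_v, Vv, Cav, t_p, spikes;
  std::vector<double> g_rec, sh_rec, e_rec;
  if (record_v) { size_t nv = (size_t)(n_steps / v_every) + 2; t_v.reserve(nv); Vv.reserve(nv); Cav.reserve(nv); }
  { size_t np = (size_t)(n_steps / p_every) + 2; t_p.reserve(np); g_rec.reserve(np * NC); sh_rec.reserve(np * NG); e_rec.reserve(np * 3); }

  int ep = 0;
  double EK = schedule(0, 2), EL = schedule(0, 3);
  double vprev1 = V, vprev2 = V, last_spike = -1e12;

  // gate -> (channel, is_inactivation) map for shifts
  // indexing identical for gates and shifts by construction

  for (long step = 0; step <= n_steps; step++) {
    double t_ms = (double)step * dt;
    // epoch switch (half-open [start, end))
    while (ep < n_ep - 1 && t_ms >= ep_end[ep]) {
      ep++;
      EK = schedule(ep, 2); EL = schedule(ep, 3);
    }

    // readouts and errors
    double Fhat = aFst, Shat = aSlw, Dhat = cD;
    double eF = Fhat - targets[0], eS = Shat - targets[1], eD = Dhat - targets[2];

    // recording
    if (record_v && (step % v_every == 0)) {
      t_v.push_back(t_ms * 1e-3); Vv.push_back(V); Cav.push_back(Ca);
    }
    if (step % p_every == 0) {
      t_p.push_back(t_ms * 1e-3);
      for (int i = 0; i < NC; i++) g_rec.push_back(g[i]);
      for (int i = 0; i < NG; i++) sh_rec.push_back(sh[i]);
      e_rec.push_back(eF); e_rec.push_back(eS); e_rec.push_back(eD);
    }
    if (step == n_steps) break;

    // effective conductances and calcium currents
    double ECa = nernstCa * std::log(caExt / std::max(Ca, 1e-6));
    double m3, h1;
    m3 = gates[0] * gates[0] * gates[0];
    double gNa  = g[0] * m3 * gates[1];
    m3 = gates[2] * gates[2] * gates[2];
    double gCaT = g[1] * m3 * gates[3];
    m3 = gates[4] * gates[4] * gates[4];
    double gCaS = g[2] * m3 * gates[5];
    m3 = gates[6] * gates[6] * gates[6];
    double gA   = g[3] * m3 * gates[7];
    h1 = gates[8] * gates[8]; h1 *= h1;
    double gKCa = g[4] * h1;
    h1 = gates[9] * gates[9]; h1 *= h1;
    double gKd  = g[5] * h1;
    double gH   = g[6] * gates[10];
    double ICaT = gCaT * (V - ECa);
    double ICaS = gCaS * (V - ECa);
    double Gtot = gNa + gCaT + gCaS + gA + gKCa + gKd + gH + gleak;
    double GE   = gNa * ENa + (gCaT + gCaS) * ECa + (gA + gKCa + gKd) * EK +
                  gH * EH + gleak * EL;

    // gate updates (exponential Euler)
    double caFac = Ca / (Ca + KhalfCa);
    if (use_tables) {
      for (int gi = 0; gi < NG; gi++) {
        double minf = inf_tab[gi].at(V - sh[gi]);
        if (gi == 8) minf *= caFac;
        double edt = edt_tab[gi].at(V);
        gates[gi] = minf + (gates[gi] - minf) * edt;
      }
    } else {
      for (int gi = 0; gi < NG; gi++) {
        double minf = gate_inf_base(gi, V - sh[gi]);
        if (gi == 8) minf *= caFac;
        double edt = std::exp(-dt / gate_tau(gi, V));
        gates[gi] = minf + (gates[gi] - minf) * edt;
      }
    }

    // calcium (forward Euler) and voltage (exponential Euler toward the
    // instantaneous resting point Vinf = GE/Gtot with time constant C/Gtot)
    double dCa = (-fCa * (ICaT + ICaS) - Ca + Ca0) / tauCa;
    Ca += dt * dCa;
    if (Ca < 0.0) Ca = 0.0;
    double Vinf = GE / Gtot;
    V = Vinf + (V - Vinf) * std::exp(-dt * Gtot / C);

    // sensor filters
    cF += aF * (Ca - cF);
    cS += aS * (Ca - cS);
    cD += aD * (Ca - cD);
    aFst += aA * (std::fabs(cF - cS) - aFst);
    aSlw += aA * (std::fabs(cS - cD) - aSlw);

    // regulation (target-normalized errors)
    if (regulate) {
      // relative errors with a dead zone: regulation engages only on
      // sustained deviations beyond the tolerance band around each target
      double e0 = eF / targets[0], e1 = eS / targets[1], e2 = eD / targets[2];
      e0 = (e0 > deadzone) ? e0 - deadzone : ((e0 < -deadzone) ? e0 + deadzone : 0.0);
      e1 = (e1 > deadzone) ? e1 - deadzone : ((e1 < -deadzone) ? e1 + deadzone : 0.0);
      e2 = (e2 > deadzone) ? e2 - deadzone : ((e2 < -deadzone) ? e2 + deadzone : 0.0);
      if (en_g) {
        double r = dts / tau_g;
        for (int i = 0; i < NC; i++) {
          double drive = Wg(i, 0) * e0 + Wg(i, 1) * e1 + Wg(i, 2) * e2;
          double fac = 1.0 - r * drive;
          if (fac < 1e-6) fac = 1e-6;
          g[i] *= fac;
        }
      }
      if (en_h) {
        for (int j = 0; j < NG; j++) {
          double drive = Wh(j, 0) * e0 + Wh(j, 1) * e1 + Wh(j, 2) * e2;
          sh[j] += dts * (-drive / tau_half - lambda * (sh[j] - anchor[j]));
        }
      }
    }

    // spike peak detection at full resolution
    if (vprev1 >= vprev2 && vprev1 > V && vprev1 >= thresh) {
      double tpk = t_ms - dt;
      if (tpk - last_spike >= refr) {
        spikes.push_back(tpk * 1e-3);
        last_spike = tpk;
      }
    }
    vprev2 = vprev1; vprev1 = V;

    if ((step & 0x3FFF) == 0) {
      if (!std::isfinite(V))
        stop("integration failure: V non-finite at t = %.3f s", t_ms * 1e-3);
      if (!std::isfinite(Ca))
        stop("integration failure: Ca non-finite at t = %.3f s", t_ms * 1e-3);
      Rcpp::checkUserInterrupt();
    }
  }
  if (!std::isfinite(V)) stop("integration failure: V non-finite at end of run");

  NumericVector gatesF(NG), gF(NC), shF(NG), filtF(5);
  for (int i = 0; i < NG; i++) { gatesF[i] = gates[i]; shF[i] = sh[i]; }
  for (int i = 0; i < NC; i++) gF[i] = g[i];
  filtF[0] = cF; filtF[1] = cS; filtF[2] = cD; filtF[3] = aFst; filtF[4] = aSlw;

  size_t np = t_p.size();
  NumericMatrix gM(np, NC), shM(np, NG), eM(np, 3);
  for (size_t r = 0; r < np; r++) {
    for (int c = 0; c < NC; c++) gM(r, c) = g_rec[r * NC + c];
    for (int c = 0; c < NG; c++) shM(r, c) = sh_rec[r * NG + c];
    for (int c = 0; c < 3; c++) eM(r, c) = e_rec[r * 3 + c];
  }

  return List::create(
    _["t_v"] = wrap(t_v), _["V"] = wrap(Vv), _["Ca"] = wrap(Cav),
    _["t_p"] = wrap(t_p), _["gmax"] = gM, _["half_shifts"] = shM,
    _["sensor_errors"] = eM, _["spike_times"] = wrap(spikes),
    _["final"] = List::create(
      _["V"] = V, _["gates"] = gatesF, _["Ca"] = Ca,
      _["filters"] = filtF, _["gmax"] = gF, _["half_shifts"] = shF,
      _["t"] = total_ms * 1e-3));
}
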