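// Fixed-step RK4 integrator for the closed-loop Fontan circulation with a
// two-compartment time-varying-elastance ventricle.
//
// State vector (8):
//   0 V_e   earlier-activated ventricular compartment volume (ml, absolute)
//   1 V_d   delayed compartment volume (ml, absolute)
//   2 V_a   atrial volume (ml, absolute)
//   3 V_sa  systemic arterial compliance stressed volume (ml)
//   4 V_sv  systemic venous compliance stressed volume (ml)
//   5 V_pa  pulmonary arterial compliance stressed volume (ml)
//   6 V_pv  pulmonary venous compliance stressed volume (ml)
//   7 Q_av  atrioventricular valve flow (ml/s, inertial state)
//
// All internal units: seconds, ml, mmHg. Valve diode flags are held fixed
// across the four RK4 stages of a step and updated between steps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Chamber {
  double Emax;  // mmHg/ml
  double Tmax;  // s
  double A;     // mmHg
  double B;     // 1/ml
  double V0;    // ml
};

struct Circuit {
  Chamber atr, ve, vd;
  double onset_a, onset_e, onset_d;  // activation onsets within the cycle (s)
  double T;                          // cycle length (s)
  double Z_sa, C_sa, R_sa, C_sv, R_sv;
  double Z_pa, C_pa, R_pa, C_pv, R_pv;
  double EOA, L_av, rho, K_av;
  double R_ao, R_ic;
};

// Cycle wrap into [0, T).
inline double wrap_cycle(double x, double T) {
  double r = x - T * std::floor(x / T);
  if (r >= T) r -= T;  // guard against floating rounding at the boundary
  return r;
}

// Raised-cosine activation: rise over Tmax, relaxation over Tmax/2.
double activation(double t, double onset, double T, double Tmax) {
  double rel = wrap_cycle(t - onset, T);
  if (rel < Tmax) return 0.5 * (1.0 - std::cos(M_PI * rel / Tmax));
  if (rel < 1.5 * Tmax)
    return 0.5 * (1.0 + std::cos(M_PI * (rel - Tmax) / (0.5 * Tmax)));
  return 0.0;
}

double ped(double V, const Chamber& c) {
  return c.A * (std::exp(c.B * (V - c.V0)) - 1.0);
}
double pes(double V, const Chamber& c) { return c.Emax * (V - c.V0); }
double pcham(double V, double e, const Chamber& c) {
  double pd = ped(V, c);
  return pd + e * (pes(V, c) - pd);
}

struct Derived {
  double P_e, P_d, P_a, P_sa, P_sv, P_pa, P_pv, P_art, P_cvp;
  double Q_av, Q_ao, Q_ic, e_e, e_d, e_a;
};

void derivs(double t, const double* y, double* dy, const Circuit& p,
            bool av_open, Derived* out) {
  const double e_e = activation(t, p.onset_e, p.T, p.ve.Tmax);
  const double e_d = activation(t, p.onset_d, p.T, p.vd.Tmax);
  const double e_a = activation(t, p.onset_a, p.T, p.atr.Tmax);
  const double P_e = pcham(y[0], e_e, p.ve);
  const double P_d = pcham(y[1], e_d, p.vd);
  const double P_a = pcham(y[2], e_a, p.atr);
  const double P_sa = y[3] / p.C_sa;
  const double P_sv = y[4] / p.C_sv;
  const double P_pa = y[5] / p.C_pa;
  const double P_pv = y[6] / p.C_pv;

  // aortic valve: ideal diode + series resistance, then characteristic
  // impedance of the systemic Windkessel
  const double Q_ao = (P_d > P_sa) ? (P_d - P_sa) / (p.R_ao + p.Z_sa) : 0.0;
  const double Q_sys = (P_sa - P_sv) / p.R_sa;
  // systemic venous resistance and pulmonary characteristic impedance are in
  // series across the cavopulmonary (TCPC) junction
  const double Q_ven = (P_sv - P_pa) / (p.R_sv + p.Z_pa);
  const double Q_pul = (P_pa - P_pv) / p.R_pa;
  const double Q_pvn = (P_pv - P_a) / p.R_pv;  // pulmonary veins -> atrium
  const double Q_av = av_open ? y[7] : 0.0;
  const double Q_ic = (P_e - P_d) / p.R_ic;    // positive: earlier -> delayed

  dy[0] = Q_av - Q_ic;
  dy[1] = Q_ic - Q_ao;
  dy[2] = Q_pvn - Q_av;
  dy[3] = Q_ao - Q_sys;
  dy[4] = Q_sys - Q_ven;
  dy[5] = Q_ven - Q_pul;
  dy[6] = Q_pul - Q_pvn;
  dy[7] = av_open
              ? (P_a - P_e -
                 p.rho * Q_av * Q_av / (2.0 * p.K_av * p.EOA * p.EOA)) /
                    p.L_av
              : 0.0;

  if (out) {
    out->P_e = P_e; out->P_d = P_d; out->P_a = P_a;
    out->P_sa = P_sa; out->P_sv = P_sv; out->P_pa = P_pa; out->P_pv = P_pv;
    out->P_art = P_sa + p.Z_sa * Q_ao;      // proximal aortic (root) node
    out->P_cvp = P_pa + p.Z_pa * Q_ven;     // TCPC junction (SVC site)
    out->Q_av = Q_av; out->Q_ao = Q_ao; out->Q_ic = Q_ic;
    out->e_e = e_e; out->e_d = e_d; out->e_a = e_a;
  }
}

Chamber chamber_from(const NumericVector& v) {
  Chamber c;
  c.Emax = v["Emax"]; c.Tmax = v["Tmax"]; c.A = v["A"];
  c.B = v["B"]; c.V0 = v["V0"];
  return c;
}

Circuit circuit_from(const List& par) {
  Circuit p;
  p.atr = chamber_from(par["atr"]);
  p.ve = chamber_from(par["ve"]);
  p.vd = chamber_from(par["vd"]);
  p.onset_a = par["onset_a"]; p.onset_e = par["onset_e"];
  p.onset_d = par["onset_d"]; p.T = par["T"];
  p.Z_sa = par["Z_sa"]; p.C_sa = par["C_sa"]; p.R_sa = par["R_sa"];
  p.C_sv = par["C_sv"]; p.R_sv = par["R_sv"];
  p.Z_pa = par["Z_pa"]; p.C_pa = par["C_pa"]; p.R_pa = par["R_pa"];
  p.C_pv = par["C_pv"]; p.R_pv = par["R_pv"];
  p.EOA = par["EOA"]; p.L_av = par["L_av"]; p.rho = par["rho"];
  p.K_av = par["K_av"]; p.R_ao = par["R_ao"]; p.R_ic = par["R_ic"];
  return p;
}

void rk4_step(double t, double h, double* y, const Circuit& p, bool av_open) {
  double k1[8], k2[8], k3[8], k4[8], yt[8];
  derivs(t, y, k1, p, av_open, nullptr);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  derivs(t + 0.5 * h, yt, k2, p, av_open, nullptr);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  derivs(t + 0.5 * h, yt, k3, p, av_open, nullptr);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + h * k3[i];
  derivs(t + h, yt, k4, p, av_open, nullptr);
  for (int i = 0; i < 8; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

}  // namespace

// [[Rcpp::export]]
List circuit_derivs_cpp(NumericVector state, double t_s, List par,
                        bool av_open) {
  if (state.size() != 8) stop("state must have length 8");
  Circuit p = circuit_from(par);
  double dy[8];
  Derived d;
  derivs(t_s, REAL(state), dy, p, av_open, &d);
  NumericVector dstate(8);
  for (int i = 0; i < 8; ++i) dstate[i] = dy[i];
  dstate.names() = CharacterVector::create("V_e", "V_d", "V_a", "V_sa", "V_sv",
                                           "V_pa", "V_pv", "Q_av");
  return List::create(
      _["dstate"] = dstate,
      _["pressures"] = NumericVector::create(
          _["P_e"] = d.P_e, _["P_d"] = d.P_d, _["P_a"] = d.P_a,
          _["P_sa"] = d.P_sa, _["P_sv"] = d.P_sv, _["P_pa"] = d.P_pa,
          _["P_pv"] = d.P_pv, _["P_art"] = d.P_art, _["P_cvp"] = d.P_cvp),
      _["flows"] = NumericVector::create(_["Q_av"] = d.Q_av, _["Q_ao"] = d.Q_ao,
                                         _["Q_ic"] = d.Q_ic),
      _["activation"] = NumericVector::create(_["e_e"] = d.e_e,
                                              _["e_d"] = d.e_d,
                                              _["e_a"] = d.e_a));
}

// [[Rcpp::export]]
List simulate_circuit_cpp(List par, NumericVector init_state, bool init_av_open,
                          double dt_s, int out_every, int min_beats,
                          int max_beats, double tol) {
  if (init_state.size() != 8) stop("init_state must have length 8");
  Circuit p = circuit_from(par);
  const long steps = std::lround(p.T / dt_s);
  if (steps < 10) stop("time step too large for the cycle length");
  if (out_every < 1 || steps % out_every != 0)
    stop("out_every must divide the steps per beat");
  const long nrow = steps / out_every + 1;
  const long onset_step = std::lround(p.onset_e / dt_s);  // EDV sampling step

  const int ncol = 19;
  NumericMatrix tr(nrow, ncol);
  CharacterVector cn2(ncol);
  const char* names[ncol] = {"t_ms", "V_e",  "V_d",  "V_a",  "P_e",  "P_d",
                             "P_a",  "P_art", "P_cvp", "P_sa", "P_sv", "P_pa",
                             "P_pv", "Q_av", "Q_ao", "Q_ic", "e_e",  "e_d",
                             "e_a"};
  for (int j = 0; j < ncol; ++j) cn2[j] = names[j];
  colnames(tr) = cn2;

  double y[8];
  for (int i = 0; i < 8; ++i) y[i] = init_state[i];
  bool av_open = init_av_open;

  std::vector<double> edv_by_beat, sv_by_beat;
  double edv_prev = NA_REAL, sv_prev = NA_REAL;
  double edv_drift = NA_REAL, sv_drift = NA_REAL;
  bool converged = false;
  int beat = 0;

  for (beat = 0; beat < max_beats; ++beat) {
    const double t0 = beat * p.T;
    double edv_beat = NA_REAL, sv_beat = 0.0;
    for (long s = 0; s < steps; ++s) {
      const double t = t0 + s * dt_s;
      Derived d;
      double dy[8];
      derivs(t, y, dy, p, av_open, &d);
      if (s % out_every == 0) {
        const long r = s / out_every;
        tr(r, 0) = s * dt_s * 1000.0;
        tr(r, 1) = y[0]; tr(r, 2) = y[1]; tr(r, 3) = y[2];
        tr(r, 4) = d.P_e; tr(r, 5) = d.P_d; tr(r, 6) = d.P_a;
        tr(r, 7) = d.P_art; tr(r, 8) = d.P_cvp; tr(r, 9) = d.P_sa;
        tr(r, 10) = d.P_sv; tr(r, 11) = d.P_pa; tr(r, 12) = d.P_pv;
        tr(r, 13) = d.Q_av; tr(r, 14) = d.Q_ao; tr(r, 15) = d.Q_ic;
        tr(r, 16) = d.e_e; tr(r, 17) = d.e_d; tr(r, 18) = d.e_a;
      }
      if (s == onset_step) edv_beat = y[0] + y[1];
      sv_beat += d.Q_ao * dt_s;  // forward aortic output per beat (ml)

      rk4_step(t, dt_s, y, p, av_open);

      // valve diode logic between steps
      if (av_open) {
        if (y[7] <= 0.0) { y[7] = 0.0; av_open = false; }
      } else {
        const double tn = t + dt_s;
        const double P_a_n =
            pcham(y[2], activation(tn, p.onset_a, p.T, p.atr.Tmax), p.atr);
        const double P_e_n =
            pcham(y[0], activation(tn, p.onset_e, p.T, p.ve.Tmax), p.ve);
        if (P_a_n > P_e_n) { av_open = true; y[7] = 0.0; }
      }
    }
    // close the beat: final sample at t = T
    {
      const double t = t0 + steps * dt_s;
      Derived d;
      double dy[8];
      derivs(t, y, dy, p, av_open, &d);
      const long r = nrow - 1;
      tr(r, 0) = steps * dt_s * 1000.0;
      tr(r, 1) = y[0]; tr(r, 2) = y[1]; tr(r, 3) = y[2];
      tr(r, 4) = d.P_e; tr(r, 5) = d.P_d; tr(r, 6) = d.P_a;
      tr(r, 7) = d.P_art; tr(r, 8) = d.P_cvp; tr(r, 9) = d.P_sa;
      tr(r, 10) = d.P_sv; tr(r, 11) = d.P_pa; tr(r, 12) = d.P_pv;
      tr(r, 13) = d.Q_av; tr(r, 14) = d.Q_ao; tr(r, 15) = d.Q_ic;
      tr(r, 16) = d.e_e; tr(r, 17) = d.e_d; tr(r, 18) = d.e_a;
    }

    for (int i = 0; i < 8; ++i)
      if (!std::isfinite(y[i]))
        stop("non-finite state at beat %d (component %d)", beat + 1, i + 1);

    edv_by_beat.push_back(edv_beat);
    sv_by_beat.push_back(sv_beat);
    if (beat > 0) {
      edv_drift = std::fabs(edv_beat - edv_prev) / std::fabs(edv_prev);
      sv_drift = std::fabs(sv_beat - sv_prev) / std::max(std::fabs(sv_prev), 1e-9);
      if (beat + 1 >= min_beats && edv_drift < tol && sv_drift < tol) {
        converged = true;
        ++beat;
        break;
      }
    }
    edv_prev = edv_beat;
    sv_prev = sv_beat;
  }

  NumericVector fin(8);
  for (int i = 0; i < 8; ++i) fin[i] = y[i];
  fin.names() = CharacterVector::create("V_e", "V_d", "V_a", "V_sa", "V_sv",
                                        "V_pa", "V_pv", "Q_av");
  return List::create(
      _["traces"] = tr, _["n_beats"] = beat, _["converged"] = converged,
      _["edv_drift"] = edv_drift, _["sv_drift"] = sv_drift,
      _["edv_by_beat"] = wrap(edv_by_beat), _["sv_by_beat"] = wrap(sv_by_beat),
      _["final_state"] = fin, _["av_open"] = av_open);
}
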