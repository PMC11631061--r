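// Closed-loop lumped-parameter circulation: four chambers (LA, LV, RA, RV),
// four diode valves (mitral with optional inertance), systemic and pulmonary
// arterial/venous compartments. Fixed-step RK4; flow antisymmetry makes the
// sum of compartment volumes an exact invariant of the scheme (to round-off).
//
// Units inside this file: seconds, mL, mmHg, mmHg.s/mL, mmHg.s^2/mL.

#include <Rcpp.h>
using namespace Rcpp;

static const int NV = 9; // 8 volumes + mitral flow state

struct Chamber {
  double V0, Eact, c, Pref, k, ton, dact, tau;
};

struct Model {
  Chamber ch[4]; // LA, LV, RA, RV
  double CL;
  double Csa, V0sa, Csv, V0sv, Cpa, V0pa, Cpv, V0pv;
  double Rsys, Rpul, Rsvra, Rpvla;
  double Rmv, Lmv, Rav, Rtv, Rpv;
  int peri_on; double Pperi, kperi, Vh0;
  int valves_open;       // lock all valves open (linear bidirectional)
  int act_const; double a_const; // freeze activation at a_const
};

static inline double clamp_exp(double x) {
  return exp(x > 50.0 ? 50.0 : x);
}

// positive modulo; result in [0, y)
static inline double pmod(double x, double y) {
  return x - std::floor(x / y) * y;
}

static inline double activation_fun(double ts, double d, double tau) {
  if (ts <= 0.0) return 0.0;
  if (ts <= d) {
    double s = sin(M_PI * ts / (2.0 * d));
    return s * s;
  }
  return exp(-(ts - d) / tau);
}

static inline double chamber_pressure_fun(const Chamber &c, double V,
                                          double a, double pperi) {
  double V0 = c.V0;
  double pa = a * c.c * c.Eact * (V - V0);
  double pp = c.Pref * (clamp_exp(c.k * (V / V0 - 1.0)) - 1.0);
  return pa + pp + pperi;
}

static Model unpack(const List &prm) {
  Model m;
  NumericMatrix ch = prm["chambers"]; // 4 x 8, rows LA LV RA RV
  for (int i = 0; i < 4; ++i) {
    m.ch[i].V0 = ch(i, 0); m.ch[i].Eact = ch(i, 1); m.ch[i].c = ch(i, 2);
    m.ch[i].Pref = ch(i, 3); m.ch[i].k = ch(i, 4); m.ch[i].ton = ch(i, 5);
    m.ch[i].dact = ch(i, 6); m.ch[i].tau = ch(i, 7);
  }
  m.CL = as<double>(prm["CL"]);
  NumericVector v = prm["vessels"]; // Csa V0sa Csv V0sv Cpa V0pa Cpv V0pv
  m.Csa = v[0]; m.V0sa = v[1]; m.Csv = v[2]; m.V0sv = v[3];
  m.Cpa = v[4]; m.V0pa = v[5]; m.Cpv = v[6]; m.V0pv = v[7];
  NumericVector r = prm["resistances"]; // Rsys Rpul Rsvra Rpvla
  m.Rsys = r[0]; m.Rpul = r[1]; m.Rsvra = r[2]; m.Rpvla = r[3];
  NumericVector vv = prm["valves"]; // Rmv Lmv Rav Rtv Rpv
  m.Rmv = vv[0]; m.Lmv = vv[1]; m.Rav = vv[2]; m.Rtv = vv[3]; m.Rpv = vv[4];
  NumericVector pc = prm["pericardium"]; // on Pperi kperi Vh0
  m.peri_on = (int) pc[0]; m.Pperi = pc[1]; m.kperi = pc[2]; m.Vh0 = pc[3];
  m.valves_open = as<int>(prm["valves_open"]);
  m.act_const = as<int>(prm["act_const"]);
  m.a_const = as<double>(prm["a_const"]);
  return m;
}

// Fill pressures p[8] (LA LV RA RV SA SV PA PV), activations a[4],
// flows q[8] (mv av sys svra tv pv pul pvla) and state derivative dy.
static void eval_model(const Model &m, double t, const double *y,
                       double *dy, double *p, double *q, double *a) {
  double tc = pmod(t, m.CL);
  double Vh = y[0] + y[1] + y[2] + y[3];
  double pperi = 0.0;
  if (m.peri_on)
    pperi = m.Pperi * pow(Vh / m.Vh0, m.kperi); // power-law pericardial sac
  for (int i = 0; i < 4; ++i) {
    if (m.act_const) {
      a[i] = m.a_const;
    } else {
      double ts = pmod(tc - m.ch[i].ton, m.CL);
      if (ts < 0) ts += m.CL;
      a[i] = activation_fun(ts, m.ch[i].dact, m.ch[i].tau);
    }
    p[i] = chamber_pressure_fun(m.ch[i], y[i], a[i], pperi);
  }
  p[4] = (y[4] - m.V0sa) / m.Csa;
  p[5] = (y[5] - m.V0sv) / m.Csv;
  p[6] = (y[6] - m.V0pa) / m.Cpa;
  p[7] = (y[7] - m.V0pv) / m.Cpv;

  double qmv, dqmv = 0.0;
  double dpmv = p[0] - p[1];
  if (m.valves_open) {
    qmv = dpmv / m.Rmv;
  } else if (m.Lmv > 0.0) {
    double qs = y[8];
    if (qs <= 0.0 && dpmv <= 0.0) {
      qmv = 0.0; dqmv = 0.0;
    } else {
      qmv = qs > 0.0 ? qs : 0.0;
      dqmv = (dpmv - m.Rmv * qmv) / m.Lmv;
    }
  } else {
    qmv = dpmv > 0.0 ? dpmv / m.Rmv : 0.0;
  }
  double qav, qtv, qpv;
  if (m.valves_open) {
    qav = (p[1] - p[4]) / m.Rav;
    qtv = (p[2] - p[3]) / m.Rtv;
    qpv = (p[3] - p[6]) / m.Rpv;
  } else {
    double d1 = p[1] - p[4]; qav = d1 > 0.0 ? d1 / m.Rav : 0.0;
    double d2 = p[2] - p[3]; qtv = d2 > 0.0 ? d2 / m.Rtv : 0.0;
    double d3 = p[3] - p[6]; qpv = d3 > 0.0 ? d3 / m.Rpv : 0.0;
  }
  double qsys = (p[4] - p[5]) / m.Rsys;
  double qsvra = (p[5] - p[2]) / m.Rsvra;
  double qpul = (p[6] - p[7]) / m.Rpul;
  double qpvla = (p[7] - p[0]) / m.Rpvla;

  q[0] = qmv; q[1] = qav; q[2] = qsys; q[3] = qsvra;
  q[4] = qtv; q[5] = qpv; q[6] = qpul; q[7] = qpvla;

  dy[0] = qpvla - qmv;
  dy[1] = qmv - qav;
  dy[2] = qsvra - qtv;
  dy[3] = qtv - qpv;
  dy[4] = qav - qsys;
  dy[5] = qsys - qsvra;
  dy[6] = qpv - qpul;
  dy[7] = qpul - qpvla;
  dy[8] = dqmv;
}

static void rk4_step(const Model &m, double t, double h, double *y) {
  double k1[NV], k2[NV], k3[NV], k4[NV], yt[NV];
  double p[8], q[8], a[4];
  eval_model(m, t, y, k1, p, q, a);
  for (int i = 0; i < NV; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  eval_model(m, t + 0.5 * h, yt, k2, p, q, a);
  for (int i = 0; i < NV; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  eval_model(m, t + 0.5 * h, yt, k3, p, q, a);
  for (int i = 0; i < NV; ++i) yt[i] = y[i] + h * k3[i];
  eval_model(m, t + h, yt, k4, p, q, a);
  for (int i = 0; i < NV; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  if (y[8] < 0.0) y[8] = 0.0; // mitral flow cannot reverse
}

// [[Rcpp::export]]
List simulate_beats_cpp(NumericVector y0, List prm, int n_beats,
                        double dt, double out_dt, int save_mode) {
  // save_mode: 0 = none, 1 = last beat only, 2 = all beats
  Model m = unpack(prm);
  int nout_beat = (int) std::lround(m.CL / out_dt);
  if (nout_beat < 2) nout_beat = 2;
  int stride = (int) std::lround(out_dt / dt);
  if (stride < 1) stride = 1;
  int nst = nout_beat * stride; // steps per beat, exact multiple of stride
  double h = m.CL / nst;

  double y[NV];
  for (int i = 0; i < NV; ++i) y[i] = y0[i];

  NumericMatrix onsets(n_beats + 1, NV);
  for (int i = 0; i < NV; ++i) onsets(0, i) = y[i];

  int save_from = (save_mode == 2) ? 0 : (save_mode == 1 ? n_beats - 1 : n_beats);
  long nrow = 0;
  if (save_mode > 0)
    nrow = (long)(n_beats - save_from) * nout_beat + 1;
  NumericMatrix traj(save_mode > 0 ? nrow : 0, save_mode > 0 ? 22 : 0);

  double p[8], q[8], a[4], dy[NV];
  long row = 0;
  for (int b = 0; b < n_beats; ++b) {
    bool saving = (save_mode > 0 && b >= save_from);
    for (int s = 0; s < nst; ++s) {
      double t = (double) b * m.CL + s * h;
      if (saving && s % stride == 0) {
        eval_model(m, t, y, dy, p, q, a);
        traj(row, 0) = t;
        for (int i = 0; i < 8; ++i) traj(row, 1 + i) = y[i];
        for (int i = 0; i < 8; ++i) traj(row, 9 + i) = p[i];
        traj(row, 17) = q[0]; traj(row, 18) = q[1];
        traj(row, 19) = q[4]; traj(row, 20) = q[5];
        traj(row, 21) = a[1];
        ++row;
      }
      rk4_step(m, t, h, y);
      if (y[0] < 0 || y[1] < 0 || y[2] < 0 || y[3] < 0)
        stop("negative chamber volume at t=%.4f s (beat %d): unstable or invalid parameters", (double) b * m.CL + (s + 1) * h, b + 1);
    }
    for (int i = 0; i < NV; ++i) onsets(b + 1, i) = y[i];
  }
  if (save_mode > 0) {
    // closing sample at the final beat boundary
    double t = (double) n_beats * m.CL;
    eval_model(m, t, y, dy, p, q, a);
    traj(row, 0) = t;
    for (int i = 0; i < 8; ++i) traj(row, 1 + i) = y[i];
    for (int i = 0; i < 8; ++i) traj(row, 9 + i) = p[i];
    traj(row, 17) = q[0]; traj(row, 18) = q[1];
    traj(row, 19) = q[4]; traj(row, 20) = q[5];
    traj(row, 21) = a[1];
  }

  NumericVector yf(NV);
  for (int i = 0; i < NV; ++i) yf[i] = y[i];
  return List::create(_["onsets"] = onsets, _["traj"] = traj,
                      _["state"] = yf);
}

// [[Rcpp::export]]
double activation_cpp(double ts, double d, double tau) {
  return activation_fun(ts, d, tau);
}
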