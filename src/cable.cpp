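// Compartmental cable solver with extracellular drive.
//
// Staggered scheme: gating variables are advanced by exact exponential
// relaxation using rates evaluated at V^n, then the membrane voltage is
// advanced by a theta-method (theta = 1 backward Euler, 0.5 Crank-Nicolson)
// on the voltage-linear system, solved exactly on the tree by Hines
// elimination (compartments are ordered so parent index < child index).
//
// Units: V mV, t ms, areas cm^2, membrane conductances mS/cm^2 (so that
// g*V is uA/cm^2), axial conductances uS (converted to mS = uA/mV),
// currents uA, Ca in mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NGATE = 9;   // m h n a ha c q tm th
static const int NCHAN = 7;   // Na K KA KCa Ca h T (column order of gdens)

// kin: NGATE x 10 matrix, per row: aform,a1..a4,bform,b1..b4
// forms: 1 linexp, 2 expdec, 3 sigmoid, 4 siginf (paired with 5 taugauss)
static inline double eval_form(int form, double V, const double* p) {
  switch (form) {
  case 1: {
    double x = V - p[1];
    double d = x / p[2];
    if (std::fabs(d) < 1e-7) return p[0] * p[2] * (1.0 + 0.5 * d);
    return p[0] * x / (1.0 - std::exp(-d));
  }
  case 2:
    return p[0] * std::exp(-(V - p[1]) / p[2]);
  case 3:
    return p[0] / (1.0 + std::exp(-(V - p[1]) / p[2]));
  }
  return NA_REAL;
}

static inline void gate_rates(const double* kinrow, double V,
                              double& alpha, double& beta) {
  int aform = (int) kinrow[0];
  if (aform == 4) {
    double xinf = 1.0 / (1.0 + std::exp((V - kinrow[1]) / kinrow[2]));
    const double* tp = kinrow + 6; // b1..b4 hold taugauss params
    double z = (V - tp[2]) / tp[3];
    double tau = tp[0] + tp[1] * std::exp(-z * z);
    alpha = xinf / tau;
    beta = (1.0 - xinf) / tau;
  } else {
    alpha = eval_form(aform, V, kinrow + 1);
    beta = eval_form((int) kinrow[5], V, kinrow + 6);
  }
}

// [[Rcpp::export(name = ".cpp_gate_rates")]]
NumericMatrix cpp_gate_rates(double V, NumericMatrix kin) {
  NumericMatrix out(kin.nrow(), 2);
  std::vector<double> row(10);
  for (int g = 0; g < kin.nrow(); ++g) {
    for (int j = 0; j < 10; ++j) row[j] = kin(g, j);
    double a, b;
    gate_rates(row.data(), V, a, b);
    out(g, 0) = a;
    out(g, 1) = b;
  }
  return out;
}

struct CaParams {
  double cao;      // mM
  double carest;   // mM
  double tau;      // ms
  double depth_cm; // shell depth, cm
  double khalf;    // K_Ca half-activation, mM
  double nernst;   // RT/(2F) * 1000, mV
};

// advance the gates a compartment actually needs; V at time n
static inline void advance_gates(double V, double dt, const double* kin,
                                 double* x, const char* need) {
  for (int g = 0; g < NGATE; ++g) {
    if (!need[g]) continue;
    double a, b;
    gate_rates(kin + 10 * g, V, a, b);
    double s = a + b;
    if (s <= 0) continue;
    double xinf = a / s;
    x[g] = xinf + (x[g] - xinf) * std::exp(-dt * s);
  }
}

// membrane conductance G [mS/cm^2] and intercept I0 [uA/cm^2] such that
// I_ion = G*V + I0; also returns the Ca-carried conductance for the pool
static inline void membrane_lin(const double* gd, const double* x, double ca,
                                double gleak, double eleak, double ena,
                                double ek, double eh, const CaParams& cp,
                                double& G, double& I0, double& gca_tot,
                                double& eca) {
  double m = x[0], h = x[1], n = x[2], a = x[3], ha = x[4], c = x[5];
  double q = x[6], tm = x[7], th = x[8];
  double gna = gd[0] * m * m * m * h;
  double gk = gd[1] * n * n * n * n;
  double gka = gd[2] * a * a * a * ha;
  double r = ca / cp.khalf;
  double fca = (r * r) / (1.0 + r * r);
  double gkca = gd[3] * fca;
  double gca = gd[4] * c * c * c;
  double gh = gd[5] * q;
  double gt = gd[6] * tm * tm * th;
  eca = cp.nernst * std::log(cp.cao / ca);
  gca_tot = gca + gt;
  G = gna + gk + gka + gkca + gca_tot + gh + gleak;
  I0 = -(gna * ena + (gk + gka + gkca) * ek + gca_tot * eca + gh * eh +
         gleak * eleak);
}

// [[Rcpp::export(name = ".cpp_run_cable")]]
List cpp_run_cable(IntegerVector parent,      // 0-based, -1 for root, sorted
                   NumericVector area,        // cm^2
                   NumericVector gax,         // uS to parent (0 for root)
                   NumericMatrix gdens,       // ncomp x 7, mS/cm^2
                   NumericVector gleak,       // mS/cm^2 per comp
                   double cm,                 // uF/cm^2
                   double eleak, double ena, double ek, double eh,
                   NumericVector phi,         // mV per uA, per comp
                   NumericVector istim,       // uA, length nt
                   NumericVector iinj,        // nA into inj_comp, length nt
                   int inj_comp,              // 0-based
                   double dt, double theta,
                   NumericMatrix state0,      // ncomp x 11: V, 9 gates, Ca
                   List ca_params,
                   bool record_all,
                   NumericMatrix kin) {
  int nc = parent.size();
  int nt = istim.size();

  CaParams cp;
  cp.cao = as<double>(ca_params["cao"]);
  cp.carest = as<double>(ca_params["carest"]);
  cp.tau = as<double>(ca_params["tau"]);
  cp.depth_cm = as<double>(ca_params["depth_cm"]);
  cp.khalf = as<double>(ca_params["khalf"]);
  cp.nernst = as<double>(ca_params["nernst"]);
  // dCa/dt [mM/ms] = -I_Ca[uA/cm^2] * 1e-3 / (2 F depth_cm)
  double cascale = 1e-3 / (2.0 * 96485.0 * cp.depth_cm);

  std::vector<double> kinv(10 * NGATE);
  for (int g = 0; g < NGATE; ++g)
    for (int j = 0; j < 10; ++j) kinv[10 * g + j] = kin(g, j);

  std::vector<double> V(nc), Ca(nc), gates(nc * NGATE);
  for (int i = 0; i < nc; ++i) {
    V[i] = state0(i, 0);
    for (int g = 0; g < NGATE; ++g) gates[i * NGATE + g] = state0(i, g + 1);
    Ca[i] = state0(i, 10);
  }

  std::vector<double> gax_ms(nc);
  for (int i = 0; i < nc; ++i) gax_ms[i] = gax[i] * 1e-3; // uS -> uA/mV

  // gates required per compartment, from its nonzero conductances
  // gate order m h n a ha c q tm th; channel order Na K KA KCa Ca h T
  std::vector<char> need(nc * NGATE, 0);
  for (int i = 0; i < nc; ++i) {
    char* nd = &need[i * NGATE];
    if (gdens(i, 0) > 0) { nd[0] = nd[1] = true; }
    if (gdens(i, 1) > 0) nd[2] = true;
    if (gdens(i, 2) > 0) { nd[3] = nd[4] = true; }
    if (gdens(i, 4) > 0) nd[5] = true;
    if (gdens(i, 5) > 0) nd[6] = true;
    if (gdens(i, 6) > 0) { nd[7] = nd[8] = true; }
  }

  NumericVector vsoma(nt + 1);
  NumericMatrix vall;
  if (record_all) vall = NumericMatrix(nt + 1, nc);
  vsoma[0] = V[0];
  if (record_all)
    for (int i = 0; i < nc; ++i) vall(0, i) = V[i];

  std::vector<double> diag(nc), off(nc), rhs(nc), G(nc), I0(nc);
  std::vector<double> gca_tot(nc), eca(nc), ve_prev(nc), ve_now(nc);

  double istim_prev = 0.0;
  for (int i = 0; i < nc; ++i) ve_prev[i] = 0.0;

  bool diverged = false;
  double t_div = NA_REAL;

  for (int it = 0; it < nt; ++it) {
    double Is = istim[it]; // held over [t_it, t_it+dt)
    for (int i = 0; i < nc; ++i) ve_now[i] = phi[i] * Is;
    double ve_old_scale = (it == 0) ? Is : istim_prev;
    // explicit part uses the field over the previous interval
    for (int i = 0; i < nc; ++i) ve_prev[i] = phi[i] * ve_old_scale;

    // 1. gates at V^n
    for (int i = 0; i < nc; ++i)
      advance_gates(V[i], dt, kinv.data(), &gates[i * NGATE],
                    &need[i * NGATE]);

    // 2. linearized membrane
    for (int i = 0; i < nc; ++i) {
      double gd[NCHAN];
      for (int c2 = 0; c2 < NCHAN; ++c2) gd[c2] = gdens(i, c2);
      membrane_lin(gd, &gates[i * NGATE], Ca[i], gleak[i], eleak, ena, ek,
                   eh, cp, G[i], I0[i], gca_tot[i], eca[i]);
    }

    // 3. assemble and solve theta-system
    double cdt = cm / dt;
    for (int i = 0; i < nc; ++i) {
      double ai = area[i];
      diag[i] = ai * cdt + theta * ai * G[i];
      off[i] = 0.0;
      double expl = -(1.0 - theta) * ai * (G[i] * V[i] + I0[i]) -
                    theta * ai * I0[i];
      rhs[i] = ai * cdt * V[i] + expl;
    }
    for (int i = 1; i < nc; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      double g = gax_ms[i];
      diag[i] += theta * g;
      diag[p] += theta * g;
      off[i] = -theta * g;
      // extracellular drive + explicit axial coupling
      double dve_new = ve_now[p] - ve_now[i];
      double dve_old = ve_prev[p] - ve_prev[i];
      double dv_old = V[p] - V[i];
      double cur_i = g * (theta * dve_new +
                          (1.0 - theta) * (dv_old + dve_old));
      rhs[i] += cur_i;
      rhs[p] -= g * (theta * dve_new) +
                g * ((1.0 - theta) * (dv_old + dve_old));
    }
    // intracellular injection (nA -> uA)
    if (inj_comp >= 0) rhs[inj_comp] += iinj[it] * 1e-3;

    // Hines elimination (children have larger indices)
    for (int i = nc - 1; i >= 1; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double f = off[i] / diag[i];
      diag[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i) {
      int p = parent[i];
      V[i] = (rhs[i] - off[i] * V[p]) / diag[i];
    }

    // 4. calcium pool (implicit removal, explicit flux at V^{n+1})
    for (int i = 0; i < nc; ++i) {
      if (gdens(i, 3) == 0.0 && gdens(i, 4) == 0.0 && gdens(i, 6) == 0.0) {
        continue; // no Ca machinery in this compartment
      }
      double ica = gca_tot[i] * (V[i] - eca[i]); // uA/cm^2, inward negative
      double src = -ica * cascale + cp.carest / cp.tau;
      double canew = (Ca[i] + dt * src) / (1.0 + dt / cp.tau);
      Ca[i] = (canew > 1e-9) ? canew : 1e-9;
    }

    vsoma[it + 1] = V[0];
    if (record_all)
      for (int i = 0; i < nc; ++i) vall(it + 1, i) = V[i];

    if (!diverged) {
      for (int i = 0; i < nc; ++i) {
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 500.0) {
          diverged = true;
          t_div = (it + 1) * dt;
          break;
        }
      }
      if (diverged) break;
    }
    istim_prev = Is;
  }

  NumericMatrix statef(nc, 11);
  for (int i = 0; i < nc; ++i) {
    statef(i, 0) = V[i];
    for (int g = 0; g < NGATE; ++g) statef(i, g + 1) = gates[i * NGATE + g];
    statef(i, 10) = Ca[i];
  }

  List out = List::create(_["v_soma"] = vsoma, _["state"] = statef,
                          _["diverged"] = diverged, _["t_diverged"] = t_div);
  if (record_all) out["v_all"] = vall;
  return out;
}
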