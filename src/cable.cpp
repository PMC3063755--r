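// Branched cable solver: backward-Euler (optionally Crank-Nicolson via
// theta) time stepping with a Hines-ordered direct tree solve per step.
// Units: v mV, t ms, capacitance nF, conductance uS, current nA.
// Gating variables advance by the exponential (cnexp) update at the
// pre-step voltage; the voltage step is then linear and unconditionally
// stable.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Rates { double am, bm, ah, bh, an, bn; };

static inline Rates hh_rates(double v, double na_shift) {
  Rates r;
  double vn = v - na_shift;
  r.am = 0.1 * vtrap(-(vn + 40.0), 10.0);
  r.bm = 4.0 * std::exp(-(vn + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(vn + 65.0) / 20.0);
  r.bh = 1.0 / (std::exp(-(vn + 35.0) / 10.0) + 1.0);
  r.an = 0.01 * vtrap(-(v + 55.0), 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

// [[Rcpp::export]]
List simulate_cable_cpp(IntegerVector parent,       // 0-based, -1 = root, parent[i] < i
                        NumericVector g_parent,     // uS, coupling to parent
                        NumericVector cap_nF,       // nF per compartment
                        NumericVector gna_uS,       // absolute uS (gnabar*area)
                        NumericVector gk_uS,
                        NumericVector gl_uS,        // leak/passive, uS
                        NumericVector ena, NumericVector ek, NumericVector el,
                        NumericVector na_shift,
                        LogicalVector active,       // integrate HH gates
                        NumericVector induced_nA,   // nA per (A/s) of dI/dt
                        NumericVector dIdt,         // A/s at step midpoints, length nsteps
                        double v_init, double dt, int nsteps,
                        IntegerVector ic_comp, NumericVector ic_amp,
                        NumericVector ic_start, NumericVector ic_dur,
                        IntegerVector syn_comp, NumericVector syn_onset,
                        NumericVector syn_gmax, NumericVector syn_tau,
                        NumericVector syn_erev,
                        IntegerVector record, int save_every) {
  const int n = parent.size();
  const int n_ic = ic_comp.size();
  const int n_syn = syn_comp.size();
  std::vector<double> v(n, v_init), m(n), h(n), ng(n);
  std::vector<double> d(n), rhs(n);

  for (int i = 0; i < n; ++i) {
    Rates r = hh_rates(v_init, na_shift[i]);
    m[i] = r.am / (r.am + r.bm);
    h[i] = r.ah / (r.ah + r.bh);
    ng[i] = r.an / (r.an + r.bn);
  }

  const int nrec = record.size();
  const int nsave = nsteps / save_every + 1;
  NumericMatrix vrec(nrec, nsave);
  NumericVector times(nsave);
  for (int k = 0; k < nrec; ++k) vrec(k, 0) = v_init;
  times[0] = 0.0;
  int isave = 1;

  for (int step = 0; step < nsteps; ++step) {
    const double t_new = (step + 1) * dt;
    const double didt = dIdt[step];
    // assemble diagonal and rhs
    for (int i = 0; i < n; ++i) {
      double gtot = gl_uS[i];
      double ge = gl_uS[i] * el[i];
      if (active[i]) {
        Rates r = hh_rates(v[i], na_shift[i]);
        double tm = 1.0 / (r.am + r.bm), th = 1.0 / (r.ah + r.bh),
               tn = 1.0 / (r.an + r.bn);
        m[i] += (r.am * tm - m[i]) * (1.0 - std::exp(-dt / tm));
        h[i] += (r.ah * th - h[i]) * (1.0 - std::exp(-dt / th));
        ng[i] += (r.an * tn - ng[i]) * (1.0 - std::exp(-dt / tn));
        double gna = gna_uS[i] * m[i] * m[i] * m[i] * h[i];
        double gk = gk_uS[i] * ng[i] * ng[i] * ng[i] * ng[i];
        gtot += gna + gk;
        ge += gna * ena[i] + gk * ek[i];
      }
      d[i] = cap_nF[i] / dt + gtot;
      rhs[i] = cap_nF[i] / dt * v[i] + ge + induced_nA[i] * didt;
    }
    // electrodes (square pulses), evaluated at the new time level
    for (int e = 0; e < n_ic; ++e) {
      if (t_new >= ic_start[e] && t_new < ic_start[e] + ic_dur[e])
        rhs[ic_comp[e]] += ic_amp[e];
    }
    // alpha-function synaptic conductances
    for (int s = 0; s < n_syn; ++s) {
      double ts = t_new - syn_onset[s];
      if (ts > 0) {
        double g = syn_gmax[s] * (ts / syn_tau[s]) *
                   std::exp(1.0 - ts / syn_tau[s]);
        d[syn_comp[s]] += g;
        rhs[syn_comp[s]] += g * syn_erev[s];
      }
    }
    // axial coupling + Hines elimination (children have larger indices)
    for (int i = 1; i < n; ++i) {
      d[i] += g_parent[i];
      d[parent[i]] += g_parent[i];
    }
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = g_parent[i] / d[i];
      d[p] -= g_parent[i] * f;
      rhs[p] += rhs[i] * f;
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_parent[i] * v[parent[i]]) / d[i];

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]))
        stop("simulation diverged at t = %f ms in compartment %d",
             t_new, i + 1);
    }
    if ((step + 1) % save_every == 0 && isave < nsave) {
      for (int k = 0; k < nrec; ++k) vrec(k, isave) = v[record[k]];
      times[isave] = t_new;
      ++isave;
    }
  }
  return List::create(_["times"] = times, _["v"] = vrec);
}
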