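// Backward-Euler compartmental cable solver on a tree.
//
// Units: voltage mV, time ms, conductance uS, capacitance nF, current nA.
// The tree system (C/dt + G) v_new = b is solved exactly each step by
// leaf-to-root elimination and root-to-leaf back-substitution (compartments
// are ordered so that parent index < child index). Channel gating states
// advance by the exponential update at the current voltage; synapses are
// difference-of-exponential two-state conductances fed by pre-drawn event
// times.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".simulate_cable_cpp")]]
List simulate_cable_cpp(IntegerVector parent,       // 0-based, -1 for root
                        NumericVector cm,           // nF
                        NumericVector g_axial,      // uS to parent
                        NumericVector g_leak,       // uS
                        double e_leak,
                        List channels,              // per channel: named list
                        List synapses,              // per synapse: named list
                        List injections,            // per injection: named list
                        double dt,
                        double t_stop,
                        double v_init,
                        IntegerVector record_comp,  // 0-based
                        double acct_start,
                        bool record_mean) {
  const int n = parent.size();
  const int nsteps = (int)std::lround(t_stop / dt);
  const int nrec = record_comp.size();

  std::vector<double> v(n, v_init), d(n), b(n);

  // --- channels -------------------------------------------------------
  const int nchan = channels.size();
  std::vector<NumericVector> ch_gbar(nchan);   // uS per compartment
  std::vector<double> ch_erev(nchan), ch_gate_fac(nchan);
  std::vector<std::vector<double>> ch_state(nchan);
  // steady-state gating tabulated on a fine voltage grid (linear interp)
  const double tab_vmin = -150.0, tab_vmax = 80.0, tab_step = 0.05;
  const int tab_n = (int)std::lround((tab_vmax - tab_vmin) / tab_step) + 1;
  std::vector<std::vector<double>> ch_tab(nchan);
  for (int c = 0; c < nchan; ++c) {
    List ch = channels[c];
    ch_gbar[c] = as<NumericVector>(ch["gbar"]);
    ch_erev[c] = as<double>(ch["e_rev"]);
    double vhalf = as<double>(ch["vhalf"]);
    double slope = as<double>(ch["slope"]);
    double sign = as<double>(ch["sign"]);
    double tau = as<double>(ch["tau"]);
    ch_gate_fac[c] = 1.0 - std::exp(-dt / tau);
    ch_tab[c].resize(tab_n);
    for (int k = 0; k < tab_n; ++k) {
      double vv = tab_vmin + k * tab_step;
      ch_tab[c][k] = 1.0 / (1.0 + std::exp(sign * (vv - vhalf) / slope));
    }
    double xinf0 =
        1.0 / (1.0 + std::exp(sign * (v_init - vhalf) / slope));
    ch_state[c].assign(n, xinf0);
  }
  const double tab_inv = 1.0 / tab_step;

  // --- synapses -------------------------------------------------------
  const int nsyn = synapses.size();
  std::vector<int> sy_comp(nsyn);
  std::vector<double> sy_erev(nsyn), sy_w(nsyn), sy_fr(nsyn), sy_fd(nsyn);
  std::vector<double> sy_A(nsyn, 0.0), sy_B(nsyn, 0.0);
  std::vector<NumericVector> sy_events(nsyn);
  std::vector<int> sy_ptr(nsyn, 0);
  std::vector<int> sy_class(nsyn);  // 0 = excitatory, 1 = inhibitory
  for (int s = 0; s < nsyn; ++s) {
    List sy = synapses[s];
    sy_comp[s] = as<int>(sy["comp"]);
    sy_erev[s] = as<double>(sy["e_rev"]);
    double tr = as<double>(sy["tau_rise"]), td = as<double>(sy["tau_decay"]);
    double tp = tr * td / (td - tr) * std::log(td / tr);
    double norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    sy_w[s] = as<double>(sy["unitary"]) * norm;  // uS, unit peak per event
    sy_fr[s] = std::exp(-dt / tr);
    sy_fd[s] = std::exp(-dt / td);
    sy_events[s] = as<NumericVector>(sy["events"]);  // sorted, ms
    sy_class[s] = as<int>(sy["cls"]);
  }

  // --- injections -----------------------------------------------------
  const int ninj = injections.size();
  std::vector<int> in_comp(ninj);
  std::vector<double> in_amp(ninj), in_freq(ninj), in_t0(ninj), in_t1(ninj);
  for (int k = 0; k < ninj; ++k) {
    List in = injections[k];
    in_comp[k] = as<int>(in["comp"]);
    in_amp[k] = as<double>(in["amp"]);
    in_freq[k] = as<double>(in["freq"]);
    in_t0[k] = as<double>(in["t_start"]);
    in_t1[k] = as<double>(in["t_end"]);
  }

  NumericMatrix vrec(record_mean ? 1 : nsteps + 1, nrec);
  std::vector<double> vsum(nrec, 0.0);
  long vsum_n = 0;
  if (!record_mean)
    for (int r = 0; r < nrec; ++r) vrec(0, r) = v[record_comp[r]];

  // conductance accounting: leak, per channel, syn exc, syn inh (uS sums)
  std::vector<double> acc_chan(nchan, 0.0);
  double acc_leak = 0.0, acc_exc = 0.0, acc_inh = 0.0;
  long acc_steps = 0;

  const double two_pi = 6.283185307179586;

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double t_next = t + dt;
    bool acct = (t_next > acct_start);

    for (int i = 0; i < n; ++i) {
      d[i] = cm[i] / dt + g_leak[i];
      b[i] = cm[i] / dt * v[i] + g_leak[i] * e_leak;
    }
    if (acct) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += g_leak[i];
      acc_leak += s;
    }

    // channels: gate update at current voltage, then add conductance
    for (int c = 0; c < nchan; ++c) {
      const double fac = ch_gate_fac[c], er = ch_erev[c];
      const NumericVector &gb = ch_gbar[c];
      const std::vector<double> &tab = ch_tab[c];
      std::vector<double> &x = ch_state[c];
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        if (gb[i] <= 0) continue;
        double vv = v[i];
        if (vv < tab_vmin) vv = tab_vmin;
        if (vv > tab_vmax) vv = tab_vmax;
        double pos = (vv - tab_vmin) * tab_inv;
        int k = (int)pos;
        if (k >= tab_n - 1) k = tab_n - 2;
        double frac = pos - k;
        double xinf = tab[k] + frac * (tab[k + 1] - tab[k]);
        x[i] += (xinf - x[i]) * fac;
        double g = gb[i] * x[i];
        d[i] += g;
        b[i] += g * er;
        s += g;
      }
      if (acct) acc_chan[c] += s;
    }

    // synapses: consume events up to t_next, decay states, add conductance
    for (int s = 0; s < nsyn; ++s) {
      const NumericVector &ev = sy_events[s];
      while (sy_ptr[s] < ev.size() && ev[sy_ptr[s]] <= t_next) {
        sy_A[s] += sy_w[s];
        sy_B[s] += sy_w[s];
        ++sy_ptr[s];
      }
      sy_A[s] *= sy_fr[s];
      sy_B[s] *= sy_fd[s];
      double g = sy_B[s] - sy_A[s];
      if (g < 0) g = 0;
      int i = sy_comp[s];
      d[i] += g;
      b[i] += g * sy_erev[s];
      if (acct) {
        if (sy_class[s] == 0) acc_exc += g; else acc_inh += g;
      }
    }

    // current injections
    for (int k = 0; k < ninj; ++k) {
      if (t_next > in_t0[k] - 0.5 * dt && t_next < in_t1[k] + 0.5 * dt) {
        double I = in_amp[k];
        if (in_freq[k] > 0)
          I *= std::sin(two_pi * in_freq[k] * (t_next - in_t0[k]) / 1000.0);
        b[in_comp[k]] += I;
      }
    }

    if (acct) ++acc_steps;

    // Hines elimination: children (higher index) into parents
    for (int i = n - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double dd = d[i] + g_axial[i];
      double f = g_axial[i] / dd;
      d[p] += g_axial[i] - g_axial[i] * f;
      b[p] += f * b[i];
      d[i] = dd;  // store augmented diagonal for back-substitution
    }
    v[0] = b[0] / d[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      v[i] = (b[i] + g_axial[i] * v[p]) / d[i];
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]))
        stop("numerical failure: non-finite voltage at compartment %d, t = %f ms",
             i + 1, t_next);
    }
    if (record_mean) {
      if (acct) {
        for (int r = 0; r < nrec; ++r) vsum[r] += v[record_comp[r]];
        ++vsum_n;
      }
    } else {
      for (int r = 0; r < nrec; ++r) vrec(step + 1, r) = v[record_comp[r]];
    }
  }
  if (record_mean) {
    double denomv = vsum_n > 0 ? (double)vsum_n : 1.0;
    for (int r = 0; r < nrec; ++r) vrec(0, r) = vsum[r] / denomv;
  }

  NumericVector acct_out(nchan + 4);
  CharacterVector acct_names(nchan + 4);
  double denom = acc_steps > 0 ? (double)acc_steps : 1.0;
  acct_out[0] = acc_leak / denom;           acct_names[0] = "leak";
  for (int c = 0; c < nchan; ++c) {
    acct_out[1 + c] = acc_chan[c] / denom;
    acct_names[1 + c] = as<std::string>(as<List>(channels[c])["name"]);
  }
  acct_out[nchan + 1] = acc_exc / denom;    acct_names[nchan + 1] = "syn_exc";
  acct_out[nchan + 2] = acc_inh / denom;    acct_names[nchan + 2] = "syn_inh";
  double tot = 0.0;
  for (int k = 0; k < nchan + 3; ++k) tot += acct_out[k];
  acct_out[nchan + 3] = tot;                acct_names[nchan + 3] = "total";
  acct_out.attr("names") = acct_names;

  return List::create(_["v"] = vrec, _["conductance"] = acct_out,
                      _["n_steps"] = nsteps);
}
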