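// Core integrator for the leaky integrate-and-fire network with
// calcium-based early-phase plasticity and tag/protein/late-phase
// dynamics, plus the analytic fast-forward used across the
// consolidation gap.  All randomness comes from R's RNG so that
// set.seed() on the R side makes runs bit-for-bit reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Par {
  double dt, tau_m, tau_syn, t_ax_delay, t_ref, R_m, V_rev, V_reset, V_th;
  double I_0, sigma_wn, h_0;
  double t_c_delay, c_pre, c_post, tau_c, tau_h, gamma_p, gamma_d;
  double theta_p, theta_d, sigma_pl, tau_p, tau_z, alpha_p, theta_tag;
  int n_e, n_i, n_stim;
};

Par get_par(const List& p) {
  Par q;
  q.dt = p["dt"]; q.tau_m = p["tau_m"]; q.tau_syn = p["tau_syn"];
  q.t_ax_delay = p["t_ax_delay"]; q.t_ref = p["t_ref"]; q.R_m = p["R_m"];
  q.V_rev = p["V_rev"]; q.V_reset = p["V_reset"]; q.V_th = p["V_th"];
  q.I_0 = p["I_0"]; q.sigma_wn = p["sigma_wn"]; q.h_0 = p["h_0"];
  q.t_c_delay = p["t_c_delay"]; q.c_pre = p["c_pre"]; q.c_post = p["c_post"];
  q.tau_c = p["tau_c"]; q.tau_h = p["tau_h"];
  q.gamma_p = p["gamma_p"]; q.gamma_d = p["gamma_d"];
  q.theta_p = p["theta_p"]; q.theta_d = p["theta_d"];
  q.sigma_pl = p["sigma_pl"]; q.tau_p = p["tau_p"]; q.tau_z = p["tau_z"];
  q.alpha_p = p["alpha_p"]; q.theta_tag = p["theta_tag"];
  q.n_e = as<int>(p["N_e"]); q.n_i = as<int>(p["N_i"]);
  q.n_stim = as<int>(p["N_stim"]);
  return q;
}

// piecewise-constant neuromodulator level: level[j] holds on
// [breaks[j], breaks[j+1])
inline double nm_at(const NumericVector& breaks, const NumericVector& levels,
                    double t) {
  int j = breaks.size() - 1;
  while (j > 0 && t < breaks[j]) --j;
  return levels[j];
}

}  // namespace

// Simulate the spiking dynamics over [t0, t1).
//
// topo: list(out_ptr, out_tgt, out_syn, static_w, syn_pre, syn_post,
//            pre_ptr, pre_syn, post_ptr, post_syn, assembly)  [0-based]
// state: list(V, V_bg, V_stim, psp, refrac, h, z, c, p)
// stim_on/off/f: epochs (sorted, non-overlapping); stim_targets: list of
//   0-based neuron id vectors per epoch.
// Returns spikes, final state, snapshots, protein trace and optional
// per-step voltage/PSP traces of selected neurons.
// [[Rcpp::export]]
List sim_spiking_cpp(List topo, List par, List state, double t0, double t1,
                     NumericVector stim_on, NumericVector stim_off,
                     NumericVector stim_f, List stim_targets,
                     NumericVector nm_breaks, NumericVector nm_levels,
                     NumericVector snapshot_times,
                     IntegerVector record_neurons,
                     double sync_interval = 0.1) {
  const Par P = get_par(par);
  const int N = P.n_e + P.n_i;
  const double dt = P.dt;
  const int n_steps = (int)std::llround((t1 - t0) / dt);
  const int d_ax = (int)std::lround(P.t_ax_delay / dt);
  const int d_c = (int)std::lround(P.t_c_delay / dt);
  const int n_ref = (int)std::lround(P.t_ref / dt);
  const int sync_steps = std::max(1, (int)std::lround(sync_interval / dt));

  // state vectors (cloned: caller keeps its copy)
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector Vbg = clone(as<NumericVector>(state["V_bg"]));
  NumericVector Vstim = clone(as<NumericVector>(state["V_stim"]));
  NumericVector psp = clone(as<NumericVector>(state["psp"]));
  IntegerVector refrac = clone(as<IntegerVector>(state["refrac"]));
  NumericVector h = clone(as<NumericVector>(state["h"]));
  NumericVector z = clone(as<NumericVector>(state["z"]));
  NumericVector cc = clone(as<NumericVector>(state["c"]));
  NumericVector p = clone(as<NumericVector>(state["p"]));

  IntegerVector out_ptr = topo["out_ptr"], out_tgt = topo["out_tgt"],
                out_syn = topo["out_syn"];
  NumericVector static_w = topo["static_w"];
  IntegerVector syn_post = topo["syn_post"];
  IntegerVector pre_ptr = topo["pre_ptr"], pre_syn = topo["pre_syn"];
  IntegerVector post_ptr = topo["post_ptr"], post_syn = topo["post_syn"];
  IntegerVector assembly = topo["assembly"];
  const int n_syn = h.size();

  const double decay_syn = std::exp(-dt / P.tau_syn);
  const double decay_c = std::exp(-dt / P.tau_c);
  const double mu_bg = P.R_m * P.I_0;
  const double sd_bg = P.R_m * P.sigma_wn * std::sqrt(dt) / P.tau_syn;
  const double a_syn = dt / P.tau_syn;
  const double a_m = dt / P.tau_m;
  const double a_p = dt / P.tau_p;

  // per-neuron protein-relevant sum of early-phase changes
  std::vector<double> S(P.n_e, 0.0);
  for (int s = 0; s < n_syn; ++s) S[syn_post[s]] += std::fabs(h[s] - P.h_0);

  // lazy synapse bookkeeping
  std::vector<int> last_sync(n_syn, 0);
  std::vector<char> is_active(n_syn, 0), is_touched(n_syn, 0);
  std::vector<int> active, touched;
  active.reserve(4096); touched.reserve(8192);
  for (int s = 0; s < n_syn; ++s) {
    if (std::fabs(h[s] - P.h_0) > 1e-12 || z[s] != 0.0 || cc[s] > 1e-12) {
      is_touched[s] = 1; touched.push_back(s);
      if (cc[s] > P.theta_d) { is_active[s] = 1; active.push_back(s); }
    }
  }

  // bring synapse s up to the start of step `step` (valid while the
  // synapse had c <= theta_d over the gap: exact decay of c and exact
  // relaxation of h toward h_0)
  auto sync_syn = [&](int s, int step) {
    int ds = step - last_sync[s];
    if (ds <= 0) return;
    cc[s] *= std::pow(decay_c, (double)ds);
    double dev = h[s] - P.h_0;
    if (dev != 0.0) {
      double ndev = dev * std::exp(-0.1 * ds * dt / P.tau_h);
      h[s] = P.h_0 + ndev;
      S[syn_post[s]] += std::fabs(ndev) - std::fabs(dev);
    }
    last_sync[s] = step;
  };
  auto touch = [&](int s) {
    if (!is_touched[s]) { is_touched[s] = 1; touched.push_back(s); }
  };
  // calcium jump on a currently inactive synapse at start of `step`
  auto add_calcium = [&](int s, double amount, int step) {
    if (is_active[s]) { cc[s] += amount; return; }
    sync_syn(s, step);
    cc[s] += amount;
    touch(s);
    if (cc[s] > P.theta_d) { is_active[s] = 1; active.push_back(s); }
  };

  // delay rings
  std::vector<std::vector<int> > ax_ring(d_ax + 1), c_ring(d_c + 1);
  // spike log
  std::vector<int> spike_step, spike_neuron;
  spike_step.reserve(1 << 16); spike_neuron.reserve(1 << 16);

  // stimulus bookkeeping
  const int n_ep = stim_on.size();
  std::vector<char> stim_flag(N, 0);
  int cur_ep = -1;  // index of epoch currently applied, -1 = none

  // snapshots
  const int n_snap = snapshot_times.size();
  std::vector<int> snap_step(n_snap);
  for (int i = 0; i < n_snap; ++i)
    snap_step[i] = (int)std::llround((snapshot_times[i] - t0) / dt);
  List snapshots(n_snap);
  int snap_idx = 0;

  // recorded traces
  const int n_rec = record_neurons.size();
  NumericMatrix rec_V(n_rec > 0 ? n_steps : 0, n_rec);
  NumericMatrix rec_psp(n_rec > 0 ? n_steps : 0, n_rec);

  // protein / neuromodulator trace, one row per sync interval
  std::vector<double> tr_t, tr_nm, tr_thpro, tr_pcore, tr_pother, tr_nact;

  const bool core_flag_needed = assembly.size() > 0;
  std::vector<char> in_core(P.n_e, 0);
  for (int i = 0; i < assembly.size(); ++i) in_core[assembly[i]] = 1;

  auto global_sync = [&](int step) {
    for (size_t k = 0; k < touched.size(); ++k) {
      int s = touched[k];
      if (!is_active[s]) sync_syn(s, step);
    }
  };
  // late-phase update over an interval of `ds` steps using current p
  auto z_update = [&](int step, int ds) {
    double dtz = ds * dt / P.tau_z;
    for (size_t k = 0; k < touched.size(); ++k) {
      int s = touched[k];
      double pp = p[syn_post[s]];
      if (pp <= 0.0) continue;
      double dev = h[s] - P.h_0;
      if (dev > P.theta_tag) {
        z[s] += dtz * pp * (1.0 - z[s]);
        if (z[s] > 1.0) z[s] = 1.0;
      } else if (-dev > P.theta_tag) {
        z[s] -= dtz * pp * (z[s] + 0.5);
        if (z[s] < -0.5) z[s] = -0.5;
      }
    }
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;

    // --- stimulus epoch bookkeeping -----------------------------------
    if (cur_ep >= 0 && t >= stim_off[cur_ep] - 1e-12) {
      IntegerVector tg = stim_targets[cur_ep];
      for (int k = 0; k < tg.size(); ++k) stim_flag[tg[k]] = 0;
      cur_ep = -1;
    }
    if (cur_ep < 0) {
      for (int e = 0; e < n_ep; ++e) {
        if (t >= stim_on[e] - 1e-12 && t < stim_off[e] - 1e-12) {
          cur_ep = e;
          IntegerVector tg = stim_targets[e];
          for (int k = 0; k < tg.size(); ++k) stim_flag[tg[k]] = 1;
          break;
        }
      }
    }
    const double f_cur = (cur_ep >= 0) ? stim_f[cur_ep] : 0.0;
    const double mu_st = P.n_stim * f_cur * P.h_0;  // stimulus OU mean, mV
    const double sd_st =
        std::sqrt(P.n_stim * f_cur) * P.h_0 * std::sqrt(dt) / P.tau_syn;

    // --- (1) deliver due spikes ---------------------------------------
    for (int i = 0; i < N; ++i) psp[i] *= decay_syn;
    {
      std::vector<int>& due = ax_ring[step % (d_ax + 1)];
      for (size_t k = 0; k < due.size(); ++k) {
        int j = due[k];
        for (int e = out_ptr[j]; e < out_ptr[j + 1]; ++e) {
          int s = out_syn[e];
          double w = (s >= 0) ? (h[s] + P.h_0 * z[s]) : static_w[e];
          psp[out_tgt[e]] += w;
        }
      }
      due.clear();
      // delayed presynaptic calcium
      std::vector<int>& duec = c_ring[step % (d_c + 1)];
      for (size_t k = 0; k < duec.size(); ++k) {
        int j = duec[k];
        for (int q = pre_ptr[j]; q < pre_ptr[j + 1]; ++q)
          add_calcium(pre_syn[q], P.c_pre, step);
      }
      duec.clear();
    }

    // --- (2) Ornstein-Uhlenbeck drives --------------------------------
    for (int i = 0; i < N; ++i) {
      Vbg[i] += a_syn * (mu_bg - Vbg[i]) + sd_bg * norm_rand();
      if (stim_flag[i] && f_cur > 0.0) {
        Vstim[i] += a_syn * (mu_st - Vstim[i]) + sd_st * norm_rand();
      } else {
        Vstim[i] -= a_syn * Vstim[i];
      }
    }

    // --- (3) plasticity step for calcium-active synapses --------------
    for (size_t k = 0; k < active.size();) {
      int s = active[k];
      double c_s = cc[s];
      bool ip = c_s > P.theta_p, idp = c_s > P.theta_d;
      double h_s = h[s];
      double dev0 = std::fabs(h_s - P.h_0);
      double drift = 0.1 * (P.h_0 - h_s);
      int nind = 0;
      if (ip) { drift += P.gamma_p * (10.0 - h_s); ++nind; }
      if (idp) { drift -= P.gamma_d * h_s; ++nind; }
      h_s += (dt / P.tau_h) * drift;
      if (nind)
        h_s += P.sigma_pl * std::sqrt((double)nind * dt / P.tau_h) * norm_rand();
      if (h_s < 0.0) h_s = 0.0; else if (h_s > 10.0) h_s = 10.0;
      h[s] = h_s;
      S[syn_post[s]] += std::fabs(h_s - P.h_0) - dev0;
      cc[s] = c_s * decay_c;
      last_sync[s] = step + 1;
      if (cc[s] <= P.theta_d) {  // below both thresholds: go dormant
        is_active[s] = 0;
        active[k] = active.back();
        active.pop_back();
      } else {
        ++k;
      }
    }

    // --- (4) protein dynamics -----------------------------------------
    {
      const double nm = nm_at(nm_breaks, nm_levels, t);
      const double theta_pro = 1.0 / (nm + 0.001);
      for (int i = 0; i < P.n_e; ++i) {
        double target = (S[i] > theta_pro) ? P.alpha_p : 0.0;
        p[i] += a_p * (target - p[i]);
      }
    }

    // --- (5) membrane update, threshold, spike enqueueing -------------
    for (int i = 0; i < N; ++i) {
      if (refrac[i] > 0) {
        V[i] = P.V_reset;
        --refrac[i];
        continue;
      }
      double v = V[i] +
          a_m * (P.V_rev - V[i] + psp[i] + Vbg[i] + Vstim[i]);
      if (!R_finite(v))
        stop("membrane potential became non-finite at t=%.4f (neuron %d)",
             t, i + 1);
      if (v >= P.V_th) {
        spike_step.push_back(step);
        spike_neuron.push_back(i);
        v = P.V_reset;
        refrac[i] = n_ref;
        ax_ring[(step + d_ax) % (d_ax + 1)].push_back(i);
        if (i < P.n_e) {
          c_ring[(step + d_c) % (d_c + 1)].push_back(i);
          // immediate postsynaptic calcium at incoming plastic synapses
          for (int q = post_ptr[i]; q < post_ptr[i + 1]; ++q)
            add_calcium(post_syn[q], P.c_post, step);
        }
      }
      V[i] = v;
    }

    // --- traces / periodic sync ---------------------------------------
    if (n_rec > 0) {
      for (int k = 0; k < n_rec; ++k) {
        rec_V(step, k) = V[record_neurons[k]];
        rec_psp(step, k) = psp[record_neurons[k]];
      }
    }
    if ((step + 1) % sync_steps == 0) {
      global_sync(step + 1);
      z_update(step + 1, sync_steps);
      const double nm = nm_at(nm_breaks, nm_levels, t);
      double pc = 0.0, po = 0.0;
      int nc = 0, no = 0;
      for (int i = 0; i < P.n_e; ++i) {
        if (core_flag_needed && in_core[i]) { pc += p[i]; ++nc; }
        else { po += p[i]; ++no; }
      }
      tr_t.push_back(t + dt);
      tr_nm.push_back(nm);
      tr_thpro.push_back(1.0 / (nm + 0.001));
      tr_pcore.push_back(nc ? pc / nc : NA_REAL);
      tr_pother.push_back(no ? po / no : NA_REAL);
      tr_nact.push_back((double)active.size());
    }
    if (snap_idx < n_snap && step + 1 == snap_step[snap_idx]) {
      global_sync(step + 1);
      snapshots[snap_idx] = List::create(
          _["t"] = t0 + (step + 1) * dt, _["h"] = clone(h),
          _["z"] = clone(z), _["p"] = clone(p));
      ++snap_idx;
    }
    if (step % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  global_sync(n_steps);

  NumericVector sp_t(spike_step.size());
  IntegerVector sp_n(spike_neuron.size());
  for (size_t k = 0; k < spike_step.size(); ++k) {
    sp_t[k] = t0 + spike_step[k] * dt;
    sp_n[k] = spike_neuron[k] + 1;  // back to 1-based
  }

  DataFrame ptrace = DataFrame::create(
      _["t"] = tr_t, _["nm"] = tr_nm, _["theta_pro"] = tr_thpro,
      _["p_core"] = tr_pcore, _["p_other"] = tr_pother,
      _["active_synapses"] = tr_nact);

  List out_state = List::create(
      _["V"] = V, _["V_bg"] = Vbg, _["V_stim"] = Vstim, _["psp"] = psp,
      _["refrac"] = refrac, _["h"] = h, _["z"] = z, _["c"] = cc, _["p"] = p);

  return List::create(
      _["spike_time"] = sp_t, _["spike_neuron"] = sp_n,
      _["state"] = out_state, _["snapshots"] = snapshots,
      _["protein_trace"] = ptrace,
      _["trace_V"] = rec_V, _["trace_psp"] = rec_psp);
}

// Analytic/coarse integration of the weight dynamics over a
// stimulation-free gap: early-phase deviations decay exponentially
// (rate 0.1/tau_h), calcium is assumed subthreshold, and the protein
// and late-phase ODEs are integrated with an Euler step of dt_ff.
// [[Rcpp::export]]
List fast_forward_cpp(NumericVector h_in, NumericVector z_in,
                      NumericVector p_in, IntegerVector syn_post, int n_e,
                      double t0, double t1,
                      NumericVector nm_breaks, NumericVector nm_levels,
                      double dt_ff, List par) {
  const Par P = get_par(par);
  if (t1 < t0) stop("fast-forward end time precedes start time");
  NumericVector z = clone(z_in), p = clone(p_in);
  const int n_syn = h_in.size();

  std::vector<double> dev0(n_syn);
  std::vector<double> S0(n_e, 0.0);
  for (int s = 0; s < n_syn; ++s) {
    dev0[s] = h_in[s] - P.h_0;
    S0[syn_post[s]] += std::fabs(dev0[s]);
  }
  // synapses currently tagged (they drop out as the decay crosses the
  // tagging threshold; none can become tagged without stimulation)
  std::vector<int> tagged;
  for (int s = 0; s < n_syn; ++s)
    if (std::fabs(dev0[s]) > P.theta_tag) tagged.push_back(s);

  const int n_full = (int)std::floor((t1 - t0) / dt_ff + 1e-9);
  const double dt_rem = (t1 - t0) - n_full * dt_ff;
  double Lambda = 1.0;

  double t = t0;
  for (int k = 0; k <= n_full; ++k) {
    const double step_dt = (k < n_full) ? dt_ff : dt_rem;
    if (step_dt <= 0.0) break;
    const double nm = nm_at(nm_breaks, nm_levels, t);
    const double theta_pro = 1.0 / (nm + 0.001);
    // protein pool, per excitatory neuron
    for (int i = 0; i < n_e; ++i) {
      double target = (S0[i] * Lambda > theta_pro) ? P.alpha_p : 0.0;
      p[i] += (step_dt / P.tau_p) * (target - p[i]);
    }
    // late phase of still-tagged synapses
    for (size_t q = 0; q < tagged.size();) {
      int s = tagged[q];
      double dev = dev0[s] * Lambda;
      if (std::fabs(dev) <= P.theta_tag) {  // tag has vanished
        tagged[q] = tagged.back();
        tagged.pop_back();
        continue;
      }
      double pp = p[syn_post[s]];
      if (pp > 0.0) {
        if (dev > 0.0) {
          z[s] += (step_dt / P.tau_z) * pp * (1.0 - z[s]);
          if (z[s] > 1.0) z[s] = 1.0;
        } else {
          z[s] -= (step_dt / P.tau_z) * pp * (z[s] + 0.5);
          if (z[s] < -0.5) z[s] = -0.5;
        }
      }
      ++q;
    }
    Lambda *= std::exp(-0.1 * step_dt / P.tau_h);
    t += step_dt;
    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector h(n_syn);
  for (int s = 0; s < n_syn; ++s) h[s] = P.h_0 + dev0[s] * Lambda;
  return List::create(_["h"] = h, _["z"] = z, _["p"] = p);
}
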