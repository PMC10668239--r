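// Forward-Euler time stepper for the AdEx excitatory/inhibitory network
// with conductance-based AMPA, GABA-A and voltage-dependent NMDA synapses.
//
// All stochastic inputs (background drive and stimulus spike trains) are
// generated on the R side and passed in as (step, train) event lists, so
// this engine is a pure function of its arguments. Delayed spike delivery
// uses per-channel ring buffers of length delay_steps + 1.
//
// NMDA gating is per presynaptic source (RS neuron or stimulus train):
// each source j carries one saturating gating pair (s_j, x_j) driven by
// its own delayed spikes, and the postsynaptic conductance is
// Q_i * sum_{j in pre(i)} s_j, modulated by the magnesium block B(V_i).
// Because s_j depends only on the spike train of source j, this is the
// per-synapse saturating-gating model at O(#sources) state.
//
// Units: mV, ms, nS, pF, pA (1 nS * 1 mV = 1 pA).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct CellPar {
  double C, gL, EL, Vth, Delta, a, b, tau_w, Vrest, v_cut;
  int refrac_steps;
};

CellPar unpack_cell(const List& par, double dt, double v_cut) {
  CellPar p;
  p.C = as<double>(par["C"]);
  p.gL = as<double>(par["g_L"]);
  p.EL = as<double>(par["E_L"]);
  p.Vth = as<double>(par["V_th"]);
  p.Delta = as<double>(par["Delta"]);
  p.a = as<double>(par["a"]);
  p.b = as<double>(par["b"]);
  p.tau_w = as<double>(par["tau_w"]);
  p.Vrest = as<double>(par["V_rest"]);
  p.v_cut = ISNAN(v_cut) ? p.Vth : v_cut;
  p.refrac_steps = (int)std::lround(as<double>(par["T_ref"]) / dt);
  return p;
}

} // namespace

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(
    int n_rs, int n_fs,
    List rs_par, List fs_par, List syn_par,
    IntegerVector rs_ptr, IntegerVector rs_tgt,
    IntegerVector fs_ptr, IntegerVector fs_tgt,
    IntegerVector ext_ptr, IntegerVector ext_tgt,
    IntegerVector stim_ptr, IntegerVector stim_tgt,
    IntegerVector ext_step, IntegerVector ext_train,
    IntegerVector stim_step, IntegerVector stim_train,
    double q_ext_ampa_bg, double q_ext_ampa_stim,
    double q_ext_nmda_rs, double q_ext_nmda_fs,
    double dt, int n_steps, int delay_steps,
    double v_cut_rs, double v_cut_fs,
    IntegerVector record_ids,
    NumericVector v0, NumericVector w0, NumericVector i_inject,
    IntegerVector forced_id, IntegerVector forced_step,
    int mean_v_every, int s_sum_every) {

  const int N = n_rs + n_fs;
  const int n_trains = ext_ptr.size() - 1;
  if (delay_steps < 1) stop("synaptic delay must be at least one time step");

  const CellPar prs = unpack_cell(rs_par, dt, v_cut_rs);
  const CellPar pfs = unpack_cell(fs_par, dt, v_cut_fs);

  const double q_ampa = as<double>(syn_par["q_ampa"]);
  const double q_gabaa = as<double>(syn_par["q_gabaa"]);
  const double q_nmda_rs = as<double>(syn_par["q_nmda_rs"]);
  const double q_nmda_fs = as<double>(syn_par["q_nmda_fs"]);
  const double tau_ampa = as<double>(syn_par["tau_ampa"]);
  const double tau_gabaa = as<double>(syn_par["tau_gabaa"]);
  const double tau_rise = as<double>(syn_par["tau_rise_nmda"]);
  const double tau_decay = as<double>(syn_par["tau_decay_nmda"]);
  const double alpha = as<double>(syn_par["alpha"]);
  const double e_ampa = as<double>(syn_par["e_ampa"]);
  const double e_gabaa = as<double>(syn_par["e_gabaa"]);
  const double e_nmda = as<double>(syn_par["e_nmda"]);
  const double mg_over = as<double>(syn_par["mg_out"]) / 3.57;

  // neuron state
  std::vector<double> V(N), w(N, 0.0), g_ampa(N, 0.0), g_gaba(N, 0.0),
      inj(N, 0.0);
  std::vector<int> refrac(N, 0);
  for (int i = 0; i < N; ++i) {
    V[i] = (v0.size() == N) ? v0[i] : (i < n_rs ? prs.EL : pfs.EL);
    if (w0.size() == N) w[i] = w0[i];
    if (i_inject.size() == N) inj[i] = i_inject[i];
  }

  // per-source NMDA gating: RS neurons and stimulus trains
  const bool use_stim_nmda = stim_step.size() > 0 &&
      (q_ext_nmda_rs != 0.0 || q_ext_nmda_fs != 0.0);
  std::vector<double> s_rs(n_rs, 0.0), x_rs(n_rs, 0.0);
  std::vector<double> s_st(use_stim_nmda ? n_trains : 0, 0.0),
      x_st(use_stim_nmda ? n_trains : 0, 0.0);
  // postsynaptic gating sums, rebuilt by scatter each step
  std::vector<double> S_rec(N, 0.0), S_ext(N, 0.0);

  // delayed-arrival ring buffers (one slot per step within the delay)
  const int n_slots = delay_steps + 1;
  std::vector<double> buf_ampa((size_t)n_slots * N, 0.0),
      buf_gaba((size_t)n_slots * N, 0.0),
      buf_xrs((size_t)n_slots * n_rs, 0.0),
      buf_xst(use_stim_nmda ? (size_t)n_slots * n_trains : 0, 0.0);

  // recording
  std::vector<int> spike_ids, spike_steps;
  spike_ids.reserve(1 << 16);
  spike_steps.reserve(1 << 16);
  const int n_mean = (n_steps + mean_v_every - 1) / mean_v_every;
  NumericVector mean_v_rs(n_mean), mean_v_fs(n_mean), mean_v_time(n_mean);
  const int n_rec = record_ids.size();
  NumericMatrix rec_v(n_rec > 0 ? n_steps : 0, n_rec),
      rec_w(n_rec > 0 ? n_steps : 0, n_rec),
      rec_gampa(n_rec > 0 ? n_steps : 0, n_rec),
      rec_ggaba(n_rec > 0 ? n_steps : 0, n_rec),
      rec_snmda(n_rec > 0 ? n_steps : 0, n_rec),
      rec_sext(n_rec > 0 ? n_steps : 0, n_rec),
      rec_iampa(n_rec > 0 ? n_steps : 0, n_rec),
      rec_igaba(n_rec > 0 ? n_steps : 0, n_rec),
      rec_inmda(n_rec > 0 ? n_steps : 0, n_rec),
      rec_arr(n_rec > 0 ? n_steps : 0, n_rec);
  std::vector<int> rec_index(N, -1);
  for (int r = 0; r < n_rec; ++r) {
    if (record_ids[r] < 1 || record_ids[r] > N) stop("record id out of range");
    rec_index[record_ids[r] - 1] = r;
  }

  // in-adjacency (post -> presynaptic sources) for the NMDA gating sums:
  // gathering reads the compact s vectors (cache-resident) instead of
  // scattering over the N-sized sum arrays
  std::vector<int> rs_in_ptr(N + 1, 0), rs_in;
  {
    for (int j = 0; j < n_rs; ++j)
      for (int k = rs_ptr[j]; k < rs_ptr[j + 1]; ++k)
        ++rs_in_ptr[rs_tgt[k]];
    for (int i = 0; i < N; ++i) rs_in_ptr[i + 1] += rs_in_ptr[i];
    rs_in.resize(rs_in_ptr[N]);
    std::vector<int> fill(rs_in_ptr.begin(), rs_in_ptr.end() - 1);
    for (int j = 0; j < n_rs; ++j)
      for (int k = rs_ptr[j]; k < rs_ptr[j + 1]; ++k)
        rs_in[fill[rs_tgt[k] - 1]++] = j;
  }
  std::vector<int> st_in_ptr, st_in;
  if (use_stim_nmda) {
    st_in_ptr.assign(N + 1, 0);
    for (int j = 0; j < n_trains; ++j)
      for (int k = stim_ptr[j]; k < stim_ptr[j + 1]; ++k)
        ++st_in_ptr[stim_tgt[k]];
    for (int i = 0; i < N; ++i) st_in_ptr[i + 1] += st_in_ptr[i];
    st_in.resize(st_in_ptr[N]);
    std::vector<int> fill(st_in_ptr.begin(), st_in_ptr.end() - 1);
    for (int j = 0; j < n_trains; ++j)
      for (int k = stim_ptr[j]; k < stim_ptr[j + 1]; ++k)
        st_in[fill[stim_tgt[k] - 1]++] = j;
  }

  std::vector<char> forced_now(N, 0);
  int ext_p = 0, stim_p = 0, forced_p = 0, mean_i = 0;
  const int n_ext_ev = ext_step.size(), n_stim_ev = stim_step.size(),
      n_forced = forced_step.size();

  std::vector<double> arr_ampa(N), arr_gaba(N);

  for (int s = 0; s < n_steps; ++s) {
    const int cur = s % n_slots;
    const int dst = (s + delay_steps) % n_slots;

    // collect arrivals scheduled for this step, then clear the slot
    double* slot_a = &buf_ampa[(size_t)cur * N];
    double* slot_g = &buf_gaba[(size_t)cur * N];
    for (int i = 0; i < N; ++i) {
      arr_ampa[i] = slot_a[i]; slot_a[i] = 0.0;
      arr_gaba[i] = slot_g[i]; slot_g[i] = 0.0;
    }

    // per-source NMDA gating update (saturating, using the pre-update x)
    {
      double* xin = &buf_xrs[(size_t)cur * n_rs];
      for (int j = 0; j < n_rs; ++j) {
        const double sj = s_rs[j];
        double sn = sj + (-sj / tau_decay + alpha * x_rs[j] * (1.0 - sj)) * dt;
        if (sn < 0.0) sn = 0.0; else if (sn > 1.0) sn = 1.0;
        x_rs[j] += -(x_rs[j] / tau_rise) * dt + xin[j];
        xin[j] = 0.0;
        s_rs[j] = sn;
      }
      if (use_stim_nmda) {
        double* xin_s = &buf_xst[(size_t)cur * n_trains];
        for (int j = 0; j < n_trains; ++j) {
          const double sj = s_st[j];
          double sn = sj + (-sj / tau_decay + alpha * x_st[j] * (1.0 - sj)) * dt;
          if (sn < 0.0) sn = 0.0; else if (sn > 1.0) sn = 1.0;
          x_st[j] += -(x_st[j] / tau_rise) * dt + xin_s[j];
          xin_s[j] = 0.0;
          s_st[j] = sn;
        }
      }
    }

    // postsynaptic NMDA gating sums (gather over in-neighbours); the
    // gating evolves on the 2-200 ms NMDA timescales, so the sums may be
    // refreshed every s_sum_every steps instead of every step
    if (s % s_sum_every == 0) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int k = rs_in_ptr[i]; k < rs_in_ptr[i + 1]; ++k)
          acc += s_rs[rs_in[k]];
        S_rec[i] = acc;
      }
      if (use_stim_nmda) {
        for (int i = 0; i < N; ++i) {
          double acc = 0.0;
          for (int k = st_in_ptr[i]; k < st_in_ptr[i + 1]; ++k)
            acc += s_st[st_in[k]];
          S_ext[i] = acc;
        }
      }
    }

    // schedule external events emitted at this step (arrive after delay)
    double* dst_a = &buf_ampa[(size_t)dst * N];
    while (ext_p < n_ext_ev && ext_step[ext_p] == s) {
      const int tr = ext_train[ext_p] - 1;
      for (int k = ext_ptr[tr]; k < ext_ptr[tr + 1]; ++k)
        dst_a[ext_tgt[k] - 1] += q_ext_ampa_bg;
      ++ext_p;
    }
    while (stim_p < n_stim_ev && stim_step[stim_p] == s) {
      const int tr = stim_train[stim_p] - 1;
      for (int k = stim_ptr[tr]; k < stim_ptr[tr + 1]; ++k)
        dst_a[stim_tgt[k] - 1] += q_ext_ampa_stim;
      if (use_stim_nmda) buf_xst[(size_t)dst * n_trains + tr] += 1.0;
      ++stim_p;
    }

    while (forced_p < n_forced && forced_step[forced_p] == s) {
      forced_now[forced_id[forced_p] - 1] = 1;
      ++forced_p;
    }

    double sum_v_rs = 0.0, sum_v_fs = 0.0;
    double* buf_a_next = dst_a;
    double* buf_g_next = &buf_gaba[(size_t)dst * N];
    double* buf_x_next = &buf_xrs[(size_t)dst * n_rs];

    for (int i = 0; i < N; ++i) {
      const bool is_rs = i < n_rs;
      const CellPar& p = is_rs ? prs : pfs;
      const double qn = is_rs ? q_nmda_rs : q_nmda_fs;
      const double qn_ext = is_rs ? q_ext_nmda_rs : q_ext_nmda_fs;

      g_ampa[i] += -(g_ampa[i] / tau_ampa) * dt + arr_ampa[i];
      g_gaba[i] += -(g_gaba[i] / tau_gabaa) * dt + arr_gaba[i];

      // synaptic currents at the pre-step voltage
      const double Vi = V[i];
      const double B = 1.0 / (1.0 + std::exp(-0.062 * Vi) * mg_over);
      const double i_ampa = g_ampa[i] * (Vi - e_ampa);
      const double i_gaba = g_gaba[i] * (Vi - e_gabaa);
      const double i_nmda =
          (qn * S_rec[i] + (use_stim_nmda ? qn_ext * S_ext[i] : 0.0)) *
          (Vi - e_nmda) * B;
      const double i_syn = i_ampa + i_gaba + i_nmda;

      // membrane / adaptation Euler step
      bool spiked = false;
      if (refrac[i] > 0) {
        V[i] = p.Vrest;
        w[i] += (p.a * (p.Vrest - p.EL) - w[i]) / p.tau_w * dt;
        --refrac[i];
      } else {
        const double v_exp = Vi < p.v_cut ? Vi : p.v_cut; // overflow guard
        const double dV = (-p.gL * (Vi - p.EL) +
                           p.gL * p.Delta * std::exp((v_exp - p.Vth) / p.Delta) -
                           w[i] - i_syn + inj[i]) / p.C;
        const double dw = (p.a * (Vi - p.EL) - w[i]) / p.tau_w;
        V[i] = Vi + dV * dt;
        w[i] += dw * dt;
        if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
          stop("non-finite state for neuron %d at t = %.2f ms", i + 1,
               (s + 1) * dt);
        if (V[i] >= p.v_cut || forced_now[i]) spiked = true;
      }
      forced_now[i] = 0;

      if (spiked) {
        spike_ids.push_back(i + 1);
        spike_steps.push_back(s);
        V[i] = p.Vrest;
        w[i] += p.b;
        refrac[i] = p.refrac_steps;
        if (is_rs) {
          for (int k = rs_ptr[i]; k < rs_ptr[i + 1]; ++k)
            buf_a_next[rs_tgt[k] - 1] += q_ampa;
          buf_x_next[i] += 1.0; // own delayed gating increment
        } else {
          const int fi = i - n_rs;
          for (int k = fs_ptr[fi]; k < fs_ptr[fi + 1]; ++k)
            buf_g_next[fs_tgt[k] - 1] += q_gabaa;
        }
      }

      if (is_rs) sum_v_rs += V[i]; else sum_v_fs += V[i];

      const int r = rec_index[i];
      if (r >= 0) {
        rec_v(s, r) = V[i];
        rec_w(s, r) = w[i];
        rec_gampa(s, r) = g_ampa[i];
        rec_ggaba(s, r) = g_gaba[i];
        rec_snmda(s, r) = S_rec[i];
        rec_sext(s, r) = use_stim_nmda ? S_ext[i] : 0.0;
        rec_iampa(s, r) = i_ampa;
        rec_igaba(s, r) = i_gaba;
        rec_inmda(s, r) = i_nmda;
        rec_arr(s, r) = arr_ampa[i];
      }
    }

    if (s % mean_v_every == 0) {
      mean_v_rs[mean_i] = sum_v_rs / n_rs;
      mean_v_fs[mean_i] = n_fs > 0 ? sum_v_fs / n_fs : NA_REAL;
      mean_v_time[mean_i] = (s + 1) * dt;
      ++mean_i;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List traces = R_NilValue;
  if (n_rec > 0) {
    traces = List::create(
        _["ids"] = record_ids, _["v"] = rec_v, _["w"] = rec_w,
        _["g_ampa"] = rec_gampa, _["g_gabaa"] = rec_ggaba,
        _["s_nmda"] = rec_snmda, _["s_nmda_ext"] = rec_sext,
        _["i_ampa"] = rec_iampa, _["i_gabaa"] = rec_igaba,
        _["i_nmda"] = rec_inmda, _["arrivals_exc"] = rec_arr);
  }
  return List::create(
      _["spike_id"] = wrap(spike_ids), _["spike_step"] = wrap(spike_steps),
      _["mean_v_time"] = mean_v_time, _["mean_v_rs"] = mean_v_rs,
      _["mean_v_fs"] = mean_v_fs, _["traces"] = traces);
}
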