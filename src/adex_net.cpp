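#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// AdEx parameter block layout (see adex_params() on the R side):
// 0:C(pF) 1:gL(nS) 2:EL(mV) 3:VT(mV) 4:DeltaT(mV) 5:a(nS) 6:b(pA)
// 7:tau_w(ms) 8:Vreset(mV) 9:Vpeak(mV) 10:t_ref(ms)
struct AdexPar {
  double C, gL, EL, VT, DeltaT, a, b, tau_w, Vreset, Vpeak, t_ref;
  explicit AdexPar(const NumericVector &p)
      : C(p[0]), gL(p[1]), EL(p[2]), VT(p[3]), DeltaT(p[4]), a(p[5]),
        b(p[6]), tau_w(p[7]), Vreset(p[8]), Vpeak(p[9]), t_ref(p[10]) {}
};

static inline double exp_term(const AdexPar &P, double V) {
  if (P.DeltaT <= 0.0) return 0.0;
  double arg = (V - P.VT) / P.DeltaT;
  if (arg < -8.0) return 0.0;  // negligible this far below threshold
  if (arg > 20.0) arg = 20.0;  // clamp: spike is imminent anyway
  return P.gL * P.DeltaT * std::exp(arg);
}

// Conductance-based AdEx network with feedforward I->E inhibition.
// Units: mV, ms, nS, pF, pA. Drive events increment g_exc of their target
// by q_drive; an I spike increments g_inh of each connected E cell by
// q_inh after delay_ms. Euler integration (dt <= 0.1 ms enforced in R).
// [[Rcpp::export]]
List adex_net_run(int n, IntegerVector is_exc,
                  NumericVector par_e, NumericVector par_i,
                  IntegerVector conn_ptr, IntegerVector conn_tgt,
                  IntegerVector drive_ptr, NumericVector drive_times,
                  double q_drive_e, double q_drive_i, double q_inh,
                  double tau_exc, double tau_inh,
                  double E_exc, double E_inh, double delay_ms,
                  double v_theta, NumericVector i_const,
                  double dt, double t_stop, IntegerVector record_idx) {
  AdexPar PE(par_e), PI(par_i);
  int n_steps = (int)std::ceil(t_stop / dt);
  int delay_steps = std::max(1, (int)std::lround(delay_ms / dt));

  std::vector<double> V(n), w(n, 0.0), ge(n, 0.0), gi(n, 0.0);
  std::vector<double> ref_until(n, -1.0), min_inet(n, 0.0);
  for (int i = 0; i < n; ++i) V[i] = is_exc[i] ? PE.EL : PI.EL;

  // bin drive events by step (counting sort)
  int n_ev = drive_times.size();
  std::vector<int> ev_step(n_ev), ev_tgt(n_ev);
  {
    int k = 0;
    for (int i = 0; i < n; ++i)
      for (int j = drive_ptr[i]; j < drive_ptr[i + 1]; ++j, ++k) {
        int s = (int)(drive_times[j] / dt);
        if (s >= n_steps) s = n_steps - 1;
        ev_step[k] = s; ev_tgt[k] = i;
      }
  }
  std::vector<int> step_cnt(n_steps + 1, 0);
  for (int k = 0; k < n_ev; ++k) step_cnt[ev_step[k] + 1]++;
  for (int s = 0; s < n_steps; ++s) step_cnt[s + 1] += step_cnt[s];
  std::vector<int> ev_by_step(n_ev);
  {
    std::vector<int> fill(step_cnt.begin(), step_cnt.end() - 1);
    for (int k = 0; k < n_ev; ++k) ev_by_step[fill[ev_step[k]]++] = ev_tgt[k];
  }

  // ring buffer of I spikes awaiting synaptic delivery
  std::vector<std::vector<int>> ring(delay_steps + 1);

  double dec_e = std::exp(-dt / tau_exc), dec_i = std::exp(-dt / tau_inh);

  std::vector<int> spk_nrn; std::vector<double> spk_t;
  int n_rec = record_idx.size();
  NumericMatrix tr_ge(n_rec, n_steps), tr_gi(n_rec, n_steps),
      tr_inet(n_rec, n_steps), tr_v(n_rec, n_steps);

  bool has_ic = i_const.size() == n;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    // deliver delayed inhibitory events due now
    std::vector<int> &due = ring[s % (delay_steps + 1)];
    for (size_t q = 0; q < due.size(); ++q) {
      int src = due[q];
      for (int j = conn_ptr[src]; j < conn_ptr[src + 1]; ++j)
        gi[conn_tgt[j]] += q_inh;
    }
    due.clear();
    // drive events at this step (FS cells get stronger unitary drive)
    for (int k = step_cnt[s]; k < step_cnt[s + 1]; ++k) {
      int tgt = ev_by_step[k];
      ge[tgt] += is_exc[tgt] ? q_drive_e : q_drive_i;
    }

    for (int i = 0; i < n; ++i) {
      const AdexPar &P = is_exc[i] ? PE : PI;
      double inet = (ge[i] * (v_theta - E_exc) + gi[i] * (v_theta - E_inh))
                    / 1000.0;  // pA -> nA
      if (inet < min_inet[i]) min_inet[i] = inet;

      double Vi = V[i];
      if (t >= ref_until[i]) {
        double Iext = has_ic ? i_const[i] : 0.0;
        double dV = (-P.gL * (Vi - P.EL) + exp_term(P, Vi)
                     - ge[i] * (Vi - E_exc) - gi[i] * (Vi - E_inh)
                     - w[i] + Iext) / P.C;
        double dw = (P.a * (Vi - P.EL) - w[i]) / P.tau_w;
        Vi += dt * dV;
        w[i] += dt * dw;
        if (Vi >= P.Vpeak || !std::isfinite(Vi)) {
          if (!std::isfinite(Vi))
            stop("integration error: non-finite membrane potential");
          spk_nrn.push_back(i); spk_t.push_back(t);
          Vi = P.Vreset;
          w[i] += P.b;
          ref_until[i] = t + P.t_ref;
          if (!is_exc[i])  // schedule feedforward inhibition
            ring[(s + delay_steps) % (delay_steps + 1)].push_back(i);
        }
      }
      V[i] = Vi;
      ge[i] *= dec_e; gi[i] *= dec_i;
    }
    for (int r = 0; r < n_rec; ++r) {
      int i = record_idx[r];
      tr_ge(r, s) = ge[i]; tr_gi(r, s) = gi[i];
      tr_inet(r, s) = (ge[i] * (v_theta - E_exc) +
                       gi[i] * (v_theta - E_inh)) / 1000.0;
      tr_v(r, s) = V[i];
    }
  }

  List traces = R_NilValue;
  if (n_rec > 0)
    traces = List::create(_["g_exc"] = tr_ge, _["g_inh"] = tr_gi,
                          _["i_net"] = tr_inet, _["v"] = tr_v);
  return List::create(
      _["spike_neuron"] = IntegerVector(spk_nrn.begin(), spk_nrn.end()),
      _["spike_time"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["min_inet"] = NumericVector(min_inet.begin(), min_inet.end()),
      _["n_steps"] = n_steps, _["dt"] = dt, _["traces"] = traces);
}

// Bernoulli sampling of I->E feedforward edges with a Gaussian
// distance-dependent probability. Uses R's RNG so that set.seed() on the
// R side makes builds reproducible. Returns CSR (ptr over all neurons,
// rows non-empty only for I cells).
// [[Rcpp::export]]
List sample_ffi_edges(int grid, IntegerVector is_exc, double pitch_um,
                      double sigma_um, double peak, double cutoff_sd) {
  RNGScope scope;
  int n = grid * grid;
  int cut_cells = (int)std::ceil(cutoff_sd * sigma_um / pitch_um);
  double two_s2 = 2.0 * sigma_um * sigma_um;
  std::vector<int> ptr(n + 1, 0);
  std::vector<int> tgt;
  tgt.reserve((size_t)n * 8);
  for (int i = 0; i < n; ++i) {
    ptr[i] = (int)tgt.size();
    if (is_exc[i]) continue;
    int r = i / grid, c = i % grid;
    int r0 = std::max(0, r - cut_cells), r1 = std::min(grid - 1, r + cut_cells);
    int c0 = std::max(0, c - cut_cells), c1 = std::min(grid - 1, c + cut_cells);
    for (int rr = r0; rr <= r1; ++rr)
      for (int cc = c0; cc <= c1; ++cc) {
        int j = rr * grid + cc;
        if (!is_exc[j]) continue;
        double dx = (cc - c) * pitch_um, dy = (rr - r) * pitch_um;
        double p = peak * std::exp(-(dx * dx + dy * dy) / two_s2);
        if (unif_rand() < p) tgt.push_back(j);
      }
  }
  ptr[n] = (int)tgt.size();
  return List::create(_["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["tgt"] = IntegerVector(tgt.begin(), tgt.end()));
}
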