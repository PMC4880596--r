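#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Electrical-phase kernel: advances a network of leaky integrate-and-fire
// neurons with delta (voltage-jump) synapses for n_steps fixed steps of size
// dt, inside one structural-plasticity interval.
//
// - Leak is integrated with the exponential (exact) update toward e_l;
//   incoming synaptic and drive events are instantaneous voltage jumps.
// - Spike propagation uses a ring buffer of pending jumps, one slot per
//   future step; per-edge delays are integer step counts >= 1 and < L where
//   L = ncol(ring).
// - Independent Poisson drive is sampled per neuron per step by inversion
//   from a cached CDF table (one table per distinct rate), using R's RNG so
//   runs are reproducible under set.seed().
// - Calcium is updated lazily: closed-form exponential decay applied at each
//   spike before the intake beta is added, and all traces are synchronised
//   to the interval end on exit.
//
// Inputs are cloned on entry and the updated buffers (v, refrac, ca, ring)
// are returned, so callers keep value semantics. Neurons are indexed 1..n
// on the R side.

struct PoisTable {
  double lambda;
  std::vector<double> cdf; // cdf[k] = P(X <= k)
};

static int sample_pois(const PoisTable& tb) {
  if (tb.lambda <= 0.0) return 0;
  if (tb.cdf.empty()) return (int)R::rpois(tb.lambda); // large-rate fallback
  double u = unif_rand();
  const std::vector<double>& c = tb.cdf;
  size_t k = 0;
  while (k < c.size() - 1 && u > c[k]) ++k;
  return (int)k;
}

// [[Rcpp::export]]
List sim_interval_cpp(NumericVector v, IntegerVector refrac, NumericVector ca,
                      NumericMatrix ring, double start_step, int n_steps,
                      double dt,
                      IntegerVector edge_pre, IntegerVector edge_post,
                      NumericVector edge_amp, IntegerVector edge_delay,
                      int n_edges,
                      NumericVector lif_decay, NumericVector lif_el,
                      NumericVector lif_vth, NumericVector lif_vreset,
                      IntegerVector lif_refsteps,
                      NumericVector drive_lambda, NumericVector drive_amp,
                      NumericVector ca_tau, NumericVector ca_beta,
                      IntegerVector ext_step, IntegerVector ext_neuron,
                      NumericVector ext_amp,
                      bool record_spikes) {
  RNGScope scope;
  v = clone(v); refrac = clone(refrac); ca = clone(ca); ring = clone(ring);
  const int n = v.size();
  const int L = ring.ncol();
  if (n_edges > edge_pre.size()) stop("n_edges exceeds edge buffer length");

  // CSR of the edge list by presynaptic neuron (counting sort, O(n + E))
  std::vector<int> ptr(n + 1, 0), idx(n_edges);
  for (int e = 0; e < n_edges; ++e) ptr[edge_pre[e]]++; // pre is 1-based
  for (int i = 0; i < n; ++i) ptr[i + 1] += ptr[i];
  {
    std::vector<int> start(n);
    for (int i = 0; i < n; ++i) start[i] = ptr[i];
    for (int e = 0; e < n_edges; ++e) idx[start[edge_pre[e] - 1]++] = e;
  }

  // Poisson CDF tables for the distinct drive rates
  std::vector<PoisTable> tables;
  std::vector<int> tab_of(n, -1);
  for (int i = 0; i < n; ++i) {
    double lam = drive_lambda[i];
    int found = -1;
    for (size_t t = 0; t < tables.size(); ++t)
      if (tables[t].lambda == lam) { found = (int)t; break; }
    if (found < 0) {
      PoisTable tb; tb.lambda = lam;
      if (lam > 0 && lam <= 30.0) {
        double p = std::exp(-lam), c = p;
        tb.cdf.push_back(c);
        int k = 0;
        while (c < 1.0 - 1e-12 && k < 200) {
          ++k;
          p *= lam / k;
          c += p;
          tb.cdf.push_back(c);
        }
      }
      tables.push_back(tb);
      found = (int)tables.size() - 1;
    }
    tab_of[i] = found;
  }

  std::vector<double> last_t(n, start_step * dt);
  std::vector<int> n_spk(n, 0);
  std::vector<double> spk_time;
  std::vector<int> spk_id;

  int ext_i = 0;
  const int n_ext = ext_step.size();

  for (int s = 0; s < n_steps; ++s) {
    const long long abs_step = (long long)(start_step + 0.5) + s;
    const int slot = (int)(abs_step % L);
    double* col = &ring(0, slot);

    // externally injected jumps scheduled for this relative step
    while (ext_i < n_ext && ext_step[ext_i] == s) {
      col[ext_neuron[ext_i] - 1] += ext_amp[ext_i];
      ++ext_i;
    }

    for (int i = 0; i < n; ++i) {
      double inp = col[i];
      if (drive_lambda[i] > 0) {
        int k = sample_pois(tables[tab_of[i]]);
        if (k > 0) inp += k * drive_amp[i];
      }
      if (refrac[i] > 0) {
        refrac[i]--;
        v[i] = lif_vreset[i];
        continue;
      }
      v[i] = lif_el[i] + (v[i] - lif_el[i]) * lif_decay[i] + inp;
      if (v[i] >= lif_vth[i]) {
        v[i] = lif_vreset[i];
        refrac[i] = lif_refsteps[i];
        const double t_sp = (abs_step + 1.0) * dt;
        ca[i] = ca[i] * std::exp(-(t_sp - last_t[i]) / ca_tau[i]) + ca_beta[i];
        last_t[i] = t_sp;
        n_spk[i]++;
        if (record_spikes) { spk_time.push_back(t_sp); spk_id.push_back(i + 1); }
        for (int q = ptr[i]; q < ptr[i + 1]; ++q) {
          const int e = idx[q];
          const int tslot = (int)((abs_step + edge_delay[e]) % L);
          ring(edge_post[e] - 1, tslot) += edge_amp[e];
        }
      }
    }
    // consumed: clear this slot
    for (int i = 0; i < n; ++i) col[i] = 0.0;
  }

  // synchronise calcium to the interval end
  const double t_end = (start_step + n_steps) * dt;
  for (int i = 0; i < n; ++i)
    ca[i] *= std::exp(-(t_end - last_t[i]) / ca_tau[i]);

  return List::create(_["v"] = v, _["refrac"] = refrac, _["ca"] = ca,
                      _["ring"] = ring,
                      _["n_spikes"] = wrap(n_spk),
                      _["spike_time"] = wrap(spk_time),
                      _["spike_neuron"] = wrap(spk_id));
}
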