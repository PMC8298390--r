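#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) on a compartmental
// lattice: mass-action reactions within compartments plus per-particle
// transport (diffusion hop / mass-flow) events along directed couplings.
//
// Event selection is two-level: a binary sum tree over per-compartment total
// propensities gives O(log n) compartment selection; the winning compartment
// is then scanned channel-by-channel with freshly computed propensities, so
// floating-point drift in the incrementally maintained totals self-corrects
// every time a compartment fires.

namespace {

struct SumTree {
  int n = 1;
  std::vector<double> t;
  void init(int n_leaves) {
    n = 1;
    while (n < n_leaves) n <<= 1;
    t.assign(2 * n, 0.0);
  }
  void set(int i, double v) {
    i += n;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) t[i] = t[2 * i] + t[2 * i + 1];
  }
  double total() const { return t[1]; }
  // sample leaf with probability proportional to its value; u in [0, total)
  int sample(double &u) const {
    int i = 1;
    while (i < n) {
      i <<= 1;
      if (u >= t[i]) { u -= t[i]; ++i; }
    }
    return i - n;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(IntegerMatrix counts0,        // n_spec x n_comp
              NumericVector comp_vol_L,     // litres
              IntegerVector r_s1,           // first reactant (0-based)
              IntegerVector r_s2,           // second reactant or -1
              NumericVector r_rate,         // 1/s or 1/(M s)
              IntegerMatrix r_delta,        // n_spec x n_reac count changes
              IntegerVector edge_ptr,       // CSR over source compartment
              IntegerVector edge_to,        // target compartment per edge
              NumericMatrix edge_rate,      // n_edge x n_spec, per-particle 1/s
              double n_scale,               // particles per mole
              NumericVector record_times,   // sorted, > 0
              double max_events,
              bool snapshots) {
  const int n_spec = counts0.nrow(), n_comp = counts0.ncol();
  const int n_reac = r_rate.size();
  const int n_rec = record_times.size();

  std::vector<double> cnt(counts0.begin(), counts0.end());  // column-major
  std::vector<double> totals(n_spec, 0.0);
  for (int c = 0; c < n_comp; ++c)
    for (int s = 0; s < n_spec; ++s) totals[s] += cnt[c * n_spec + s];

  const double v_tot = sum(comp_vol_L);

  // per-compartment bimolecular volume factor
  std::vector<double> inv_nv(n_comp);
  for (int c = 0; c < n_comp; ++c) inv_nv[c] = 1.0 / (n_scale * comp_vol_L[c]);

  auto comp_prop = [&](int c) -> double {
    const double *x = &cnt[c * n_spec];
    double a = 0.0;
    for (int j = 0; j < n_reac; ++j) {
      int s1 = r_s1[j], s2 = r_s2[j];
      if (s2 < 0) {
        a += r_rate[j] * x[s1];
      } else if (s1 == s2) {
        a += r_rate[j] * inv_nv[c] * 0.5 * x[s1] * (x[s1] - 1.0);
      } else {
        a += r_rate[j] * inv_nv[c] * x[s1] * x[s2];
      }
    }
    for (int e = edge_ptr[c]; e < edge_ptr[c + 1]; ++e)
      for (int s = 0; s < n_spec; ++s) a += edge_rate(e, s) * x[s];
    return a;
  };

  SumTree tree;
  tree.init(n_comp);
  for (int c = 0; c < n_comp; ++c) tree.set(c, comp_prop(c));

  NumericMatrix rec(n_rec, n_spec);         // volume-averaged molar
  List snaps(snapshots ? n_rec : 0);
  auto record_now = [&](int ri) {
    for (int s = 0; s < n_spec; ++s)
      rec(ri, s) = totals[s] / (n_scale * v_tot);
    if (snapshots) {
      IntegerMatrix m(n_spec, n_comp);
      for (int i = 0; i < n_spec * n_comp; ++i)
        m[i] = (int)cnt[i];
      snaps[ri] = m;
    }
  };

  int max_edges = 0;
  for (int c = 0; c < n_comp; ++c)
    max_edges = std::max(max_edges, edge_ptr[c + 1] - edge_ptr[c]);
  std::vector<double> props(n_reac + max_edges * n_spec);

  double t = 0.0, n_events = 0.0;
  int ri = 0;
  std::string status = "ok";
  const double t_end = n_rec ? record_times[n_rec - 1] : 0.0;

  while (ri < n_rec) {
    double a_tot = tree.total();
    if (a_tot <= 0.0) {               // absorbed: state can never change again
      status = "absorbed";
      while (ri < n_rec) record_now(ri++);
      break;
    }
    if (n_events >= max_events) {
      status = "event_budget";
      while (ri < n_rec) record_now(ri++);
      break;
    }
    double dt = exp_rand() / a_tot;
    double t_next = t + dt;
    while (ri < n_rec && record_times[ri] <= t_next) record_now(ri++);
    t = t_next;
    if (t > t_end) break;

    double u = unif_rand() * a_tot;
    int c = tree.sample(u);
    if (c >= n_comp) c = n_comp - 1;   // guard: numerical edge of the tree

    // rescan channels with fresh propensities (also fixes tree drift)
    double *x = &cnt[c * n_spec];
    const int e0 = edge_ptr[c], e1 = edge_ptr[c + 1];
    const int n_chan = n_reac + (e1 - e0) * n_spec;
    double fresh = 0.0;
    for (int j = 0; j < n_reac; ++j) {
      int s1 = r_s1[j], s2 = r_s2[j];
      double p;
      if (s2 < 0) p = r_rate[j] * x[s1];
      else if (s1 == s2) p = r_rate[j] * inv_nv[c] * 0.5 * x[s1] * (x[s1] - 1.0);
      else p = r_rate[j] * inv_nv[c] * x[s1] * x[s2];
      props[j] = p;
      fresh += p;
    }
    {
      int k = n_reac;
      for (int e = e0; e < e1; ++e)
        for (int s = 0; s < n_spec; ++s, ++k) {
          double p = edge_rate(e, s) * x[s];
          props[k] = p;
          fresh += p;
        }
    }
    if (u >= fresh) {  // stale (too large) tree leaf: resync and retry
      tree.set(c, fresh);
      continue;
    }
    int hit_reac = -1, hit_edge = -1, hit_spec = -1;
    {
      double acc = 0.0;
      int k = 0;
      for (; k < n_chan; ++k) {
        acc += props[k];
        if (u < acc && props[k] > 0.0) break;
      }
      if (k >= n_chan) {  // numerical edge: resynchronise and retry
        tree.set(c, fresh);
        continue;
      }
      if (k < n_reac) {
        hit_reac = k;
      } else {
        int kk = k - n_reac;
        hit_edge = e0 + kk / n_spec;
        hit_spec = kk % n_spec;
      }
    }

    if (hit_reac >= 0) {
      for (int s = 0; s < n_spec; ++s) {
        int d = r_delta(s, hit_reac);
        if (d) { x[s] += d; totals[s] += d; }
      }
      tree.set(c, comp_prop(c));
    } else {
      int c2 = edge_to[hit_edge];
      x[hit_spec] -= 1.0;
      cnt[c2 * n_spec + hit_spec] += 1.0;
      tree.set(c, comp_prop(c));
      tree.set(c2, comp_prop(c2));
    }
    n_events += 1.0;
  }

  return List::create(
    _["concentrations"] = rec,
    _["final_counts"] = [&]() {
      IntegerMatrix m(n_spec, n_comp);
      for (int i = 0; i < n_spec * n_comp; ++i) m[i] = (int)cnt[i];
      return m;
    }(),
    _["n_events"] = n_events,
    _["status"] = status,
    _["snapshots"] = snaps);
}
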