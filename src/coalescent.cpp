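#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Piecewise-constant-Ne heterochronous coalescent.
//
// Time axis: generations before the reference date, increasing into the past.
// Epoch e covers [breaks[e-1], breaks[e]) with an implicit 0 lower bound for
// e = 0; the final epoch (index = breaks.size()) is unbounded, so coalescence
// always completes.  Within an epoch of diploid size N the waiting time to the
// next coalescence among k lineages is Exp(k(k-1)/(4N)); epoch boundaries and
// lineage entry events truncate waits (valid by memorylessness).

struct Genealogy {
  std::vector<double> time;   // node times, tips first
  std::vector<int> parent;    // 0-based parent index, -1 for root
};

static Genealogy sim_genealogy_core(const std::vector<double>& tip_time,
                                    const NumericVector& breaks,
                                    const NumericVector& sizes) {
  const int n = (int) tip_time.size();
  const int n_nodes = 2 * n - 1;
  Genealogy g;
  g.time.assign(n_nodes, 0.0);
  g.parent.assign(n_nodes, -1);

  // entrants sorted by sampling time (ascending = most recent first)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) { ord[i] = i; g.time[i] = tip_time[i]; }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return tip_time[a] < tip_time[b]; });

  std::vector<int> active;
  active.reserve(n);
  int i_ent = 0;
  const int nb = breaks.size();
  double t = tip_time[ord[0]];
  int epoch = 0;
  while (epoch < nb && breaks[epoch] <= t) ++epoch;
  while (i_ent < n && tip_time[ord[i_ent]] <= t) active.push_back(ord[i_ent++]);

  int next_node = n;
  while ((int) active.size() > 1 || i_ent < n) {
    double next_ent = (i_ent < n) ? tip_time[ord[i_ent]] : R_PosInf;
    double next_brk = (epoch < nb) ? breaks[epoch] : R_PosInf;
    double horizon = std::min(next_ent, next_brk);
    int k = (int) active.size();
    double wait = R_PosInf;
    if (k >= 2) {
      double rate = (double) k * (k - 1) / (4.0 * sizes[epoch]);
      wait = exp_rand() / rate;
    }
    if (t + wait < horizon) {
      t += wait;
      int i1 = (int) (unif_rand() * k); if (i1 == k) i1 = k - 1;
      int i2 = (int) (unif_rand() * (k - 1)); if (i2 == k - 1) i2 = k - 2;
      if (i2 >= i1) ++i2;
      int a = active[i1], b = active[i2];
      int p = next_node++;
      g.time[p] = t;
      g.parent[a] = p;
      g.parent[b] = p;
      active[i1] = p;
      active[i2] = active.back();
      active.pop_back();
    } else {
      t = horizon;
      while (i_ent < n && tip_time[ord[i_ent]] <= t) active.push_back(ord[i_ent++]);
      while (epoch < nb && breaks[epoch] <= t) ++epoch;
    }
  }
  return g;
}

// Generalized stepwise mutation: counts ~ Poisson(mu * branch length), step
// magnitudes 1 + Geometric(1 - P) (P = 0 gives the strict single-step SMM),
// signs symmetric, allele states reflected into [1, n_states].
static inline int reflect_state(long a, int S) {
  // fold into [1, S]; period of the reflected walk is 2(S-1)
  if (S <= 1) return 1;
  long m = 2L * (S - 1);
  long x = (a - 1) % m;
  if (x < 0) x += m;
  if (x >= S - 1 && m > 0) x = m - x;
  return (int) (x + 1);
}

static void drop_mutations_core(const Genealogy& g, int n_tips,
                                double mu, double P, int n_states,
                                int root_state, std::vector<int>& allele) {
  const int n_nodes = (int) g.time.size();
  allele.assign(n_nodes, 0);
  for (int id = n_nodes - 1; id >= 0; --id) {
    if (g.parent[id] < 0) { allele[id] = root_state; continue; }
    double br = g.time[g.parent[id]] - g.time[id];
    int nm = (int) R::rpois(mu * br);
    long a = allele[g.parent[id]];
    for (int m = 0; m < nm; ++m) {
      long step = 1 + (P > 0.0 ? (long) R::rgeom(1.0 - P) : 0L);
      if (unif_rand() < 0.5) step = -step;
      a = reflect_state(a + step, n_states);
    }
    allele[id] = reflect_state(a, n_states);
  }
}

// [[Rcpp::export(name = "cpp_sim_genealogy")]]
List cpp_sim_genealogy(NumericVector tip_times, NumericVector breaks,
                       NumericVector sizes) {
  std::vector<double> tt(tip_times.begin(), tip_times.end());
  Genealogy g = sim_genealogy_core(tt, breaks, sizes);
  int n_nodes = (int) g.time.size();
  IntegerVector parent(n_nodes);
  NumericVector time(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    parent[i] = g.parent[i] + 1;  // 1-based, 0 = root
    time[i] = g.time[i];
  }
  return List::create(_["parent"] = parent, _["time"] = time,
                      _["n_tips"] = (int) tt.size());
}

// [[Rcpp::export(name = "cpp_drop_mutations")]]
IntegerVector cpp_drop_mutations(IntegerVector parent, NumericVector time,
                                 int n_tips, double mu, double P,
                                 int n_states, int root_state) {
  Genealogy g;
  int n_nodes = parent.size();
  g.time.assign(time.begin(), time.end());
  g.parent.resize(n_nodes);
  for (int i = 0; i < n_nodes; ++i) g.parent[i] = parent[i] - 1;
  std::vector<int> allele;
  drop_mutations_core(g, n_tips, mu, P, n_states, root_state, allele);
  IntegerVector out(n_tips);
  for (int i = 0; i < n_tips; ++i) out[i] = allele[i];
  return out;
}

// Simulate a full temporal dataset: one independent genealogy per locus, two
// gene copies per individual entering at the individual's sampling time.
// Returns an n_ind x (2 * n_loci) matrix of allele states in repeat units.
// [[Rcpp::export(name = "cpp_sim_dataset")]]
IntegerMatrix cpp_sim_dataset(IntegerVector group_sizes,
                              NumericVector group_times,
                              NumericVector breaks, NumericVector sizes,
                              NumericVector mu_locus, double P,
                              int n_states, int root_state) {
  const int G = group_sizes.size();
  int n_ind = 0;
  for (int gi = 0; gi < G; ++gi) n_ind += group_sizes[gi];
  const int n_tips = 2 * n_ind;
  const int L = mu_locus.size();
  std::vector<double> tip_time(n_tips);
  {
    int k = 0;
    for (int gi = 0; gi < G; ++gi)
      for (int i = 0; i < group_sizes[gi]; ++i) {
        tip_time[k++] = group_times[gi];
        tip_time[k++] = group_times[gi];
      }
  }
  IntegerMatrix out(n_ind, 2 * L);
  std::vector<int> allele;
  for (int l = 0; l < L; ++l) {
    Genealogy g = sim_genealogy_core(tip_time, breaks, sizes);
    drop_mutations_core(g, n_tips, mu_locus[l], P, n_states, root_state, allele);
    for (int i = 0; i < n_ind; ++i) {
      out(i, 2 * l) = allele[2 * i];
      out(i, 2 * l + 1) = allele[2 * i + 1];
    }
  }
  return out;
}
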