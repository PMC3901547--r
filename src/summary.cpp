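#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Fast path for the temporal summary-statistic vector.  Layout (G groups):
//   A[1..G], He[1..G], V[1..G], M[1..G],               one-sample, locus means
//   A2, He2, V2 on pooled adjacent pairs [G-1 each],   two-sample, locus means
//   FST (Weir-Cockerham, ratio of sums) [G-1]          adjacent pairs
// Missing alleles are NA; a locus contributes to a group's means only when it
// has >= 2 typed gene copies there; FST uses complete individuals only.

struct LocusGroup {
  std::map<int, int> counts;     // allele -> copy count
  int copies = 0;
  double sum = 0.0, sumsq = 0.0; // of allele sizes
};

static void acc_copy(LocusGroup& lg, int a) {
  lg.counts[a] += 1;
  lg.copies += 1;
  lg.sum += a;
  lg.sumsq += (double) a * a;
}

// A, He (unbiased), V (unbiased), M from accumulated copies
static bool one_sample(const LocusGroup& lg, double& A, double& He,
                       double& V, double& M) {
  if (lg.copies < 2) return false;
  double c = lg.copies, ssq = 0.0, ssd = 0.0;
  double mean = lg.sum / c;
  int amin = lg.counts.begin()->first, amax = lg.counts.rbegin()->first;
  for (auto& kv : lg.counts) {
    double p = kv.second / c;
    ssq += p * p;
    ssd += kv.second * (kv.first - mean) * (kv.first - mean);
  }
  A = (double) lg.counts.size();
  He = c / (c - 1.0) * (1.0 - ssq);
  V = ssd / (c - 1.0);
  M = A / ((double) (amax - amin) + 1.0);
  return true;
}

// [[Rcpp::export(name = "cpp_stat_vector")]]
NumericVector cpp_stat_vector(IntegerMatrix geno, IntegerVector group_sizes,
                              int n_loci) {
  const int G = group_sizes.size();
  const int P = G - 1;
  std::vector<int> g0(G);  // first row of each group
  {
    int acc = 0;
    for (int g = 0; g < G; ++g) { g0[g] = acc; acc += group_sizes[g]; }
  }
  NumericVector out(4 * G + 4 * P);
  std::vector<double> sumA(G, 0), sumHe(G, 0), sumV(G, 0), sumM(G, 0);
  std::vector<int> nlocA(G, 0);
  std::vector<double> sumA2(P, 0), sumHe2(P, 0), sumV2(P, 0);
  std::vector<int> nloc2(P, 0);
  std::vector<double> fst_num(P, 0), fst_den(P, 0);

  std::vector<LocusGroup> lg(G);
  for (int l = 0; l < n_loci; ++l) {
    for (int g = 0; g < G; ++g) lg[g] = LocusGroup();
    // per-group accumulation; het counts per allele for WC need individuals
    std::vector<std::map<int, int>> het(G);   // allele -> het-individual count
    std::vector<std::map<int, int>> cnt_c(G); // allele counts, complete inds
    std::vector<int> n_complete(G, 0);
    for (int g = 0; g < G; ++g) {
      for (int i = 0; i < group_sizes[g]; ++i) {
        int a1 = geno(g0[g] + i, 2 * l);
        int a2 = geno(g0[g] + i, 2 * l + 1);
        bool ok1 = a1 != NA_INTEGER, ok2 = a2 != NA_INTEGER;
        if (ok1) acc_copy(lg[g], a1);
        if (ok2) acc_copy(lg[g], a2);
        if (ok1 && ok2) {
          n_complete[g] += 1;
          cnt_c[g][a1] += 1;
          cnt_c[g][a2] += 1;
          if (a1 != a2) { het[g][a1] += 1; het[g][a2] += 1; }
        }
      }
      double A, He, V, M;
      if (one_sample(lg[g], A, He, V, M)) {
        sumA[g] += A; sumHe[g] += He; sumV[g] += V; sumM[g] += M;
        nlocA[g] += 1;
      }
    }
    for (int p = 0; p < P; ++p) {
      // pooled adjacent pair
      LocusGroup pooled = lg[p];
      for (auto& kv : lg[p + 1].counts) pooled.counts[kv.first] += kv.second;
      pooled.copies += lg[p + 1].copies;
      pooled.sum += lg[p + 1].sum;
      pooled.sumsq += lg[p + 1].sumsq;
      double A, He, V, M;
      if (one_sample(pooled, A, He, V, M)) {
        sumA2[p] += A; sumHe2[p] += He; sumV2[p] += V;
        nloc2[p] += 1;
      }
      // Weir-Cockerham components, r = 2 populations
      double n1 = n_complete[p], n2 = n_complete[p + 1];
      if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) continue;
      double nbar = (n1 + n2) / 2.0;
      double nc = 2.0 * nbar - (n1 * n1 + n2 * n2) / (2.0 * nbar);
      std::map<int, int> alleles;
      for (auto& kv : cnt_c[p]) alleles[kv.first] = 1;
      for (auto& kv : cnt_c[p + 1]) alleles[kv.first] = 1;
      for (auto& kv : alleles) {
        int al = kv.first;
        auto get = [&](std::map<int, int>& m) {
          auto it = m.find(al);
          return it == m.end() ? 0 : it->second;
        };
        double p1 = get(cnt_c[p]) / (2.0 * n1);
        double p2 = get(cnt_c[p + 1]) / (2.0 * n2);
        double h1 = get(het[p]) / n1;
        double h2 = get(het[p + 1]) / n2;
        double pbar = (n1 * p1 + n2 * p2) / (2.0 * nbar);
        double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                     n2 * (p2 - pbar) * (p2 - pbar)) / nbar;
        double hbar = (n1 * h1 + n2 * h2) / (2.0 * nbar);
        double inner = pbar * (1.0 - pbar) - 0.5 * s2 - 0.25 * hbar;
        double a_c = (nbar / nc) * (s2 - inner / (nbar - 1.0));
        double b_c = (nbar / (nbar - 1.0)) *
          (pbar * (1.0 - pbar) - 0.5 * s2 - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        double c_c = 0.5 * hbar;
        fst_num[p] += a_c;
        fst_den[p] += a_c + b_c + c_c;
      }
    }
  }
  for (int g = 0; g < G; ++g) {
    double d = nlocA[g] > 0 ? nlocA[g] : NA_REAL;
    out[g] = sumA[g] / d;
    out[G + g] = sumHe[g] / d;
    out[2 * G + g] = sumV[g] / d;
    out[3 * G + g] = sumM[g] / d;
  }
  for (int p = 0; p < P; ++p) {
    double d = nloc2[p] > 0 ? nloc2[p] : NA_REAL;
    out[4 * G + p] = sumA2[p] / d;
    out[4 * G + P + p] = sumHe2[p] / d;
    out[4 * G + 2 * P + p] = sumV2[p] / d;
    out[4 * G + 3 * P + p] = fst_den[p] != 0 ? fst_num[p] / fst_den[p] : 0.0;
  }
  return out;
}
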