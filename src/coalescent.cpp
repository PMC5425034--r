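// Structured-coalescent simulation core with piecewise-constant population
// sizes, generalized stepwise microsatellite mutation (GSM), a single
// nucleotide indel (SNI) overlay, and the DIYABC-style summary statistics.
//
// All randomness goes through R's RNG (RNGScope injected by Rcpp attributes),
// so set.seed() on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Piecewise-constant size lookup: epochs is (pop, start, end, size), 1-based
// pop ids. Linear scan; epoch counts are tiny (<= 3 per population).
static double size_at(const NumericMatrix& epochs, int pop, double t) {
  for (int i = 0; i < epochs.nrow(); ++i) {
    if ((int)epochs(i, 0) == pop && t >= epochs(i, 1) && t < epochs(i, 2))
      return epochs(i, 3);
  }
  stop("no epoch covers time %f for population %d", t, pop);
  return NA_REAL; // unreachable
}

// Simulate one genealogy for n = 2 * sum(sample_sizes) gene copies under an
// epoch plan. Tips are numbered 0..n-1 in population-major order (the two
// copies of an individual adjacent); internal nodes follow in coalescence
// order; the root's parent is -1. Times are in generations before present.
//
// Coalescence within a population of diploid size N happens at rate
// k(k-1)/(4N) for k lineages (1/(2N) per ordered-unordered pair); waiting
// times are exponential, truncated at epoch boundaries and merge events
// (memorylessness makes the re-draw exact).
// [[Rcpp::export]]
List cpp_sim_genealogy(NumericMatrix epochs, NumericMatrix merges,
                       IntegerVector sample_sizes) {
  int n_pop_sampled = sample_sizes.size();
  int max_pop = 0;
  for (int i = 0; i < epochs.nrow(); ++i)
    max_pop = std::max(max_pop, (int)epochs(i, 0));

  int n_tips = 0;
  for (int p = 0; p < n_pop_sampled; ++p) n_tips += 2 * sample_sizes[p];
  if (n_tips < 2) stop("need at least 2 gene copies in total");

  int n_nodes = 2 * n_tips - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> ntime(n_nodes, 0.0);
  std::vector<int> npop(n_nodes, 0);

  // active lineages per population (1-based index, slot 0 unused)
  std::vector< std::vector<int> > active(max_pop + 1);
  int tip = 0;
  for (int p = 0; p < n_pop_sampled; ++p) {
    for (int c = 0; c < 2 * sample_sizes[p]; ++c) {
      active[p + 1].push_back(tip);
      npop[tip] = p + 1;
      ++tip;
    }
  }

  // event horizon: epoch starts and merge times
  std::set<double> brk;
  for (int i = 0; i < epochs.nrow(); ++i) brk.insert(epochs(i, 1));
  for (int i = 0; i < merges.nrow(); ++i) brk.insert(merges(i, 0));

  double t = 0.0;
  int next_node = n_tips;
  int n_active = n_tips;

  while (n_active > 1) {
    // next boundary strictly after t
    double tb = R_PosInf;
    for (std::set<double>::const_iterator it = brk.upper_bound(t);
         it != brk.end(); ++it) { tb = *it; break; }

    // per-population coalescence rates
    double total_rate = 0.0;
    std::vector<double> rate(max_pop + 1, 0.0);
    for (int p = 1; p <= max_pop; ++p) {
      int k = (int)active[p].size();
      if (k >= 2) {
        double N = size_at(epochs, p, t);
        rate[p] = (double)k * (k - 1) / (4.0 * N);
        total_rate += rate[p];
      }
    }

    double wait = (total_rate > 0.0) ? ::Rf_rexp(1.0 / total_rate) : R_PosInf;

    if (t + wait < tb) {
      t += wait;
      // choose the population proportionally to its rate
      double u = ::unif_rand() * total_rate;
      int pop = 0;
      double acc = 0.0;
      for (int p = 1; p <= max_pop; ++p) {
        acc += rate[p];
        if (u <= acc && rate[p] > 0.0) { pop = p; break; }
      }
      if (pop == 0) { // numerical edge: take the last population with rate > 0
        for (int p = max_pop; p >= 1; --p) if (rate[p] > 0.0) { pop = p; break; }
      }
      // choose an unordered pair uniformly
      int k = (int)active[pop].size();
      int i = (int)std::floor(::unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)std::floor(::unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = active[pop][i], b = active[pop][j];
      int node = next_node++;
      parent[a] = node; parent[b] = node;
      ntime[node] = t; npop[node] = pop;
      // replace a by the new node, drop b
      active[pop][i] = node;
      active[pop].erase(active[pop].begin() + j);
      --n_active;
    } else {
      if (!R_FINITE(tb))
        stop("coalescent cannot complete: no events possible after t=%f", t);
      t = tb;
      for (int m = 0; m < merges.nrow(); ++m) {
        if (merges(m, 0) == tb) {
          int src = (int)merges(m, 1), dst = (int)merges(m, 2);
          for (size_t i = 0; i < active[src].size(); ++i)
            active[dst].push_back(active[src][i]);
          active[src].clear();
        }
      }
    }
  }

  return List::create(_["parent"] = wrap(parent),
                      _["time"] = wrap(ntime),
                      _["pop"] = wrap(npop),
                      _["n_tips"] = n_tips);
}

// Drop GSM + SNI mutations on a genealogy and return tip allele states.
// Mutation counts on a branch of length b are Poisson(mu*b); each GSM
// mutation moves the repeat count by +/- k with fair sign and
// P(k) = (1-p) p^(k-1) (geometric, mean 1/(1-p)); each SNI event moves the
// indel offset by +/- 1 nucleotide.
// [[Rcpp::export]]
List cpp_mutate(IntegerVector parent, NumericVector ntime, int n_tips,
                double mu, double p, double sni, int root_repeat) {
  if (p < 0.0 || p >= 1.0) stop("geometric parameter p must be in [0, 1)");
  int n_nodes = parent.size();
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) if (parent[i] < 0) root = i;

  // process nodes in decreasing time order (root first): parents always
  // precede children because node times strictly increase rootward
  std::vector<int> ord(n_nodes);
  for (int i = 0; i < n_nodes; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ntime[a] > ntime[b];
  });

  std::vector<int> rep(n_nodes, root_repeat), off(n_nodes, 0);
  for (size_t idx = 0; idx < ord.size(); ++idx) {
    int v = ord[idx];
    if (v == root) continue;
    int pa = parent[v];
    double b = ntime[pa] - ntime[v];
    int r = rep[pa], o = off[pa];
    if (mu > 0.0 && b > 0.0) {
      int nmut = (int)::Rf_rpois(mu * b);
      for (int m = 0; m < nmut; ++m) {
        int k = 1 + (p > 0.0 ? (int)::Rf_rgeom(1.0 - p) : 0);
        r += (::unif_rand() < 0.5) ? k : -k;
      }
    }
    if (sni > 0.0 && b > 0.0) {
      int nsni = (int)::Rf_rpois(sni * b);
      for (int m = 0; m < nsni; ++m) o += (::unif_rand() < 0.5) ? 1 : -1;
    }
    rep[v] = r; off[v] = o;
  }

  IntegerVector tr(n_tips), to(n_tips);
  for (int i = 0; i < n_tips; ++i) { tr[i] = rep[i]; to[i] = off[i]; }
  return List::create(_["repeat_count"] = tr, _["indel_offset"] = to);
}

// One multilocus dataset: a fresh genealogy per locus (loci unlinked),
// mutations dropped independently. Returns gene-copy x locus matrices of
// repeat counts and indel offsets, tips in population-major order.
// [[Rcpp::export]]
List cpp_sim_dataset(NumericMatrix epochs, NumericMatrix merges,
                     IntegerVector sample_sizes, int n_loci,
                     double mu, double p, double sni, int root_repeat) {
  int n_tips = 0;
  for (int i = 0; i < sample_sizes.size(); ++i) n_tips += 2 * sample_sizes[i];
  IntegerMatrix repm(n_tips, n_loci), offm(n_tips, n_loci);
  for (int l = 0; l < n_loci; ++l) {
    List g = cpp_sim_genealogy(epochs, merges, sample_sizes);
    List st = cpp_mutate(g["parent"], g["time"], n_tips, mu, p, sni,
                         root_repeat);
    IntegerVector r = st["repeat_count"], o = st["indel_offset"];
    for (int i = 0; i < n_tips; ++i) { repm(i, l) = r[i]; offm(i, l) = o[i]; }
  }
  return List::create(_["repeat_count"] = repm, _["indel_offset"] = offm);
}

// Allele identity key: two gene copies carry the same allele iff both the
// repeat count and the indel offset match.
static inline long long allele_key(int rep, int off) {
  return (long long)rep * 100000LL + (long long)(off + 50000);
}

// DIYABC-style summary-statistic vector for P populations:
//   per population (3P values): mean number of alleles, mean genetic
//     diversity (unbiased expected heterozygosity), mean allele-size
//     variance (sizes in nucleotides = motif * repeat + offset);
//   per population pair (4 * P(P-1)/2 values): pooled mean number of
//     alleles, pooled mean genetic diversity, Weir-Cockerham Fst
//     (ratio-of-sums over loci and alleles), shared-allele distance DAS.
// Rows of the matrices are gene copies in population-major order with the
// two copies of each diploid individual adjacent. Loci are processed one
// at a time: allele keys, per-population allele counts and per-allele
// heterozygote counts are built in a single pass and reused by every
// statistic.
// [[Rcpp::export]]
NumericVector cpp_summary_stats(IntegerMatrix repm, IntegerMatrix offm,
                                IntegerVector n_ind, int motif_len) {
  int P = n_ind.size(), L = repm.ncol();
  int n_rows = repm.nrow();
  std::vector<int> row0(P + 1, 0); // first gene-copy row of each population
  for (int p = 0; p < P; ++p) row0[p + 1] = row0[p] + 2 * n_ind[p];
  if (row0[P] != n_rows) stop("row count does not match sample sizes");

  int n_pairs = P * (P - 1) / 2;
  int n_stats = 3 * P + 4 * n_pairs;
  NumericVector out(n_stats);

  std::vector<double> sum_nall(P, 0.0), sum_div(P, 0.0), sum_var(P, 0.0);
  std::vector<double> pr_nall(n_pairs, 0.0), pr_div(n_pairs, 0.0);
  std::vector<double> th_num(n_pairs, 0.0), th_den(n_pairs, 0.0);
  std::vector<double> das_sum(n_pairs, 0.0);
  std::vector<long long> das_n(n_pairs, 0);

  std::vector<long long> key(n_rows);
  // per population: allele count map and per-allele heterozygote count map
  std::vector< std::map<long long, int> > cnt(P), het(P);

  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n_rows; ++i)
      key[i] = allele_key(repm(i, l), offm(i, l));

    for (int p = 0; p < P; ++p) {
      cnt[p].clear(); het[p].clear();
      double s = 0.0, s2 = 0.0;
      for (int i = row0[p]; i < row0[p + 1]; ++i) {
        cnt[p][key[i]]++;
        double sz = motif_len * (double)repm(i, l) + (double)offm(i, l);
        s += sz; s2 += sz * sz;
      }
      for (int i = row0[p]; i < row0[p + 1]; i += 2) {
        if (key[i] != key[i + 1]) { het[p][key[i]]++; het[p][key[i + 1]]++; }
      }
      int nc = 2 * n_ind[p];
      double sumsq = 0.0;
      for (std::map<long long, int>::iterator it = cnt[p].begin();
           it != cnt[p].end(); ++it) {
        double f = (double)it->second / nc;
        sumsq += f * f;
      }
      sum_nall[p] += (double)cnt[p].size();
      if (nc > 1) {
        sum_div[p] += (double)nc / (nc - 1) * (1.0 - sumsq);
        sum_var[p] += (s2 - s * s / nc) / (nc - 1);
      }
    }

    int pair = 0;
    for (int pa = 0; pa < P; ++pa) for (int pb = pa + 1; pb < P; ++pb) {
      int n1 = n_ind[pa], n2 = n_ind[pb];
      int nc1 = 2 * n1, nc2 = 2 * n2, ncp = nc1 + nc2;

      // pooled allele counts = union of the two count maps
      std::map<long long, int> cp(cnt[pa]);
      for (std::map<long long, int>::iterator it = cnt[pb].begin();
           it != cnt[pb].end(); ++it) cp[it->first] += it->second;
      double sumsq = 0.0;
      for (std::map<long long, int>::iterator it = cp.begin();
           it != cp.end(); ++it) {
        double f = (double)it->second / ncp;
        sumsq += f * f;
      }
      pr_nall[pair] += (double)cp.size();
      pr_div[pair] += (double)ncp / (ncp - 1) * (1.0 - sumsq);

      // Weir-Cockerham variance components (r = 2), summed over alleles
      double nbar = (n1 + n2) / 2.0;
      double ncoef = (n1 + n2 -
                      ((double)n1 * n1 + (double)n2 * n2) / (n1 + n2));
      for (std::map<long long, int>::iterator it = cp.begin();
           it != cp.end(); ++it) {
        long long k = it->first;
        std::map<long long, int>::iterator f1 = cnt[pa].find(k);
        std::map<long long, int>::iterator f2 = cnt[pb].find(k);
        double p1 = (f1 != cnt[pa].end() ? (double)f1->second : 0.0) / nc1;
        double p2 = (f2 != cnt[pb].end() ? (double)f2->second : 0.0) / nc2;
        std::map<long long, int>::iterator g1 = het[pa].find(k);
        std::map<long long, int>::iterator g2 = het[pb].find(k);
        double h1 = (g1 != het[pa].end() ? (double)g1->second : 0.0) / n1;
        double h2 = (g2 != het[pb].end() ? (double)g2->second : 0.0) / n2;
        double pbar = (n1 * p1 + n2 * p2) / (n1 + n2);
        double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                     n2 * (p2 - pbar) * (p2 - pbar)) / nbar; // /(r-1)=1
        double hbar = (n1 * h1 + n2 * h2) / (n1 + n2);
        double a = nbar / ncoef *
          (s2 - (pbar * (1.0 - pbar) - s2 / 2.0 - hbar / 4.0) / (nbar - 1.0));
        double b = nbar / (nbar - 1.0) *
          (pbar * (1.0 - pbar) - s2 / 2.0 -
           (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        double c = hbar / 2.0;
        th_num[pair] += a;
        th_den[pair] += a + b + c;
      }

      // shared-allele distance contributions over inter-population
      // individual pairs
      for (int i = row0[pa]; i < row0[pa + 1]; i += 2) {
        long long a1 = key[i], a2 = key[i + 1];
        for (int j = row0[pb]; j < row0[pb + 1]; j += 2) {
          long long b1 = key[j], b2 = key[j + 1];
          int shared;
          if (a1 == a2) {
            shared = (b1 == a1) + (b2 == a1);
          } else {
            shared = ((a1 == b1 || a1 == b2) ? 1 : 0) +
                     ((a2 == b1 || a2 == b2) ? 1 : 0);
            if (shared == 2 && b1 == b2) shared = 1;
          }
          das_sum[pair] += shared / 2.0;
          ++das_n[pair];
        }
      }
      ++pair;
    }
  }

  int pos = 0;
  for (int p = 0; p < P; ++p) {
    out[pos++] = sum_nall[p] / L;
    out[pos++] = sum_div[p] / L;
    out[pos++] = sum_var[p] / L;
  }
  for (int pair = 0; pair < n_pairs; ++pair) {
    out[pos++] = pr_nall[pair] / L;
    out[pos++] = pr_div[pair] / L;
    out[pos++] = (th_den[pair] != 0.0) ? th_num[pair] / th_den[pair]
                                       : NA_REAL;
    out[pos++] = 1.0 - das_sum[pair] / (double)das_n[pair];
  }
  return out;
}
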