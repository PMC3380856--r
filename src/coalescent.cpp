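// Structured-coalescent simulators: an (optionally hierarchical) island
// model used for the F_ST-outlier null distribution, and a three-deme
// settlement demography with exponential size change down to a single
// ancestral population.
//
// Both simulators archive every branch of the genealogy (its length and the
// set of sampled chromosomes it subtends) and place mutations uniformly on
// total branch length (infinite sites, fixed number of segregating sites).
// Every non-root branch subtends a proper subset of the sample, so each
// mutation is guaranteed polymorphic in the pooled sample.
//
// All randomness comes from R's RNG (unif_rand / exp_rand), so results are
// reproducible with set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Genealogy {
  std::vector<double> blen;               // archived branch lengths
  std::vector<std::vector<int> > bdesc;   // subtended sample indices
  double tmrca = 0.0;

  double total_length() const {
    double L = 0.0;
    for (double l : blen) L += l;
    return L;
  }
  // sample a branch index proportional to length
  int sample_branch() const {
    double u = unif_rand() * total_length();
    double acc = 0.0;
    for (size_t b = 0; b < blen.size(); ++b) {
      acc += blen[b];
      if (u <= acc) return (int)b;
    }
    return (int)blen.size() - 1;
  }
};

struct Lineages {
  std::vector<int> deme;                  // per lineage
  std::vector<double> birth;
  std::vector<std::vector<int> > desc;
  std::vector<int> active;                // indices into the vectors above

  void init(const IntegerVector& sample_deme) {
    int n = sample_deme.size();
    deme.assign(n, 0);
    birth.assign(n, 0.0);
    desc.assign(n, std::vector<int>());
    active.resize(n);
    for (int i = 0; i < n; ++i) {
      deme[i] = sample_deme[i];
      desc[i].push_back(i);
      active[i] = i;
    }
  }
  // close two lineages at time t, archive their branches, start the parent
  void coalesce(int ai, int aj, double t, Genealogy& gen) {
    int li = active[ai], lj = active[aj];
    gen.blen.push_back(t - birth[li]);
    gen.bdesc.push_back(desc[li]);
    gen.blen.push_back(t - birth[lj]);
    gen.bdesc.push_back(desc[lj]);
    std::vector<int> merged(desc[li]);
    merged.insert(merged.end(), desc[lj].begin(), desc[lj].end());
    deme.push_back(deme[li]);
    birth.push_back(t);
    desc.push_back(merged);
    int parent = (int)deme.size() - 1;
    // remove the two children (erase higher index first), add parent
    if (ai < aj) std::swap(ai, aj);
    active.erase(active.begin() + ai);
    active.erase(active.begin() + aj);
    active.push_back(parent);
  }
};

int pick_other_deme_uniform(int cur, int n_demes) {
  int d = (int)std::floor(unif_rand() * (n_demes - 1));
  if (d >= cur) ++d;
  return d;
}

} // namespace

// Island-model coalescent for one SNP.
// sample_deme: 0-based deme index per sampled chromosome.
// deme_group:  0-based group index per deme (length n_demes); groups must
//              have equal numbers of demes.
// m_within:    per-generation probability a lineage moves to some other deme
//              of its own group; m_between: to some deme of another group.
// Returns the derived-allele indicator per sampled chromosome plus tree
// summaries.
// [[Rcpp::export]]
List island_snp_cpp(IntegerVector sample_deme, int n_demes,
                    IntegerVector deme_group, double deme_size,
                    double m_within, double m_between) {
  int n = sample_deme.size();
  int n_groups = 0;
  for (int d = 0; d < n_demes; ++d)
    n_groups = std::max(n_groups, deme_group[d] + 1);
  std::vector<int> gsize(n_groups, 0);
  for (int d = 0; d < n_demes; ++d) gsize[deme_group[d]]++;
  // demes of each group, for migration destinations
  std::vector<std::vector<int> > gdemes(n_groups);
  for (int d = 0; d < n_demes; ++d) gdemes[deme_group[d]].push_back(d);

  double cr = 1.0 / (2.0 * deme_size);    // pair coalescence rate / gen
  double mw_eff = (gsize[0] > 1) ? m_within : 0.0;
  double mb_eff = (n_groups > 1) ? m_between : 0.0;
  double m_tot = mw_eff + mb_eff;

  Lineages lin;
  lin.init(sample_deme);
  Genealogy gen;
  std::vector<int> cnt(n_demes, 0);
  for (int i = 0; i < n; ++i) cnt[sample_deme[i]]++;
  double t = 0.0;

  while (lin.active.size() > 1) {
    double coal = 0.0;
    for (int d = 0; d < n_demes; ++d)
      coal += cnt[d] * (cnt[d] - 1) / 2.0 * cr;
    double mig = lin.active.size() * m_tot;
    double tot = coal + mig;
    if (tot <= 0.0)
      stop("lineages occupy multiple demes but migration rates are zero");
    t += R::exp_rand() / tot;
    double u = unif_rand() * tot;
    if (u < coal) {
      // choose deme proportional to its pair count
      double acc = 0.0; int d = -1;
      for (int dd = 0; dd < n_demes; ++dd) {
        acc += cnt[dd] * (cnt[dd] - 1) / 2.0 * cr;
        if (u <= acc) { d = dd; break; }
      }
      if (d < 0) d = n_demes - 1;
      // two distinct active lineages in deme d, uniformly
      std::vector<int> here;
      for (size_t a = 0; a < lin.active.size(); ++a)
        if (lin.deme[lin.active[a]] == d) here.push_back((int)a);
      int i1 = (int)std::floor(unif_rand() * here.size());
      int i2 = (int)std::floor(unif_rand() * (here.size() - 1));
      if (i2 >= i1) ++i2;
      lin.coalesce(here[i1], here[i2], t, gen);
      cnt[d]--;
    } else {
      int a = (int)std::floor(unif_rand() * lin.active.size());
      int li = lin.active[a];
      int cur = lin.deme[li];
      int dest;
      if (unif_rand() * m_tot < mw_eff) {
        // within-group move: uniform among the other demes of the group
        const std::vector<int>& ds = gdemes[deme_group[cur]];
        int j = (int)std::floor(unif_rand() * (ds.size() - 1));
        int pos = 0; dest = cur;
        for (size_t q = 0; q < ds.size(); ++q) {
          if (ds[q] == cur) continue;
          if (pos == j) { dest = ds[q]; break; }
          ++pos;
        }
      } else {
        // between-group move: uniform among demes of other groups
        int n_other = n_demes - gsize[deme_group[cur]];
        int j = (int)std::floor(unif_rand() * n_other);
        int pos = 0; dest = cur;
        for (int d = 0; d < n_demes; ++d) {
          if (deme_group[d] == deme_group[cur]) continue;
          if (pos == j) { dest = d; break; }
          ++pos;
        }
      }
      cnt[cur]--; cnt[dest]++;
      lin.deme[li] = dest;
    }
  }
  gen.tmrca = t;

  int b = gen.sample_branch();
  LogicalVector derived(n, false);
  for (int leaf : gen.bdesc[b]) derived[leaf] = true;
  return List::create(_["derived"] = derived,
                      _["tmrca"] = gen.tmrca,
                      _["tree_length"] = gen.total_length());
}

// Three-deme settlement coalescent: demes of diploid size `present_size`
// shrink exponentially backwards to `ancestral_size` at `split_gen`
// generations, where they merge into a single constant-size ancestral
// population.  `migration` is the per-generation, per-lineage probability of
// moving to a uniformly chosen other deme before the split (0 by default on
// the R side).  Places n_snps mutations on one genealogy and returns
// derived counts per deme for each.
// [[Rcpp::export]]
List settlement_snps_cpp(IntegerVector sample_deme, int n_demes,
                         double present_size, double ancestral_size,
                         double split_gen, double migration, int n_snps) {
  int n = sample_deme.size();
  double g = (split_gen > 0.0) ? std::log(present_size / ancestral_size) /
                                   split_gen
                               : 0.0;
  Lineages lin;
  lin.init(sample_deme);
  Genealogy gen;
  std::vector<int> cnt(n_demes, 0);
  for (int i = 0; i < n; ++i) cnt[sample_deme[i]]++;
  double t = 0.0;
  const double INF = std::numeric_limits<double>::infinity();

  // phase 1: separate demes, time-inhomogeneous coalescence
  while (lin.active.size() > 1 && t < split_gen) {
    double best = INF;
    int best_deme = -1;
    bool best_is_mig = false;
    for (int d = 0; d < n_demes; ++d) {
      if (cnt[d] < 2) continue;
      double Nt = present_size * std::exp(-g * t);
      double lam0 = cnt[d] * (cnt[d] - 1) / 2.0 / (2.0 * Nt);
      double E = R::exp_rand();
      double s = (g > 0.0) ? std::log1p(g * E / lam0) / g : E / lam0;
      if (s < best) { best = s; best_deme = d; best_is_mig = false; }
    }
    if (migration > 0.0 && n_demes > 1) {
      double s = R::exp_rand() / (lin.active.size() * migration);
      if (s < best) { best = s; best_is_mig = true; }
    }
    if (t + best >= split_gen || best == INF) { t = split_gen; break; }
    t += best;
    if (best_is_mig) {
      int a = (int)std::floor(unif_rand() * lin.active.size());
      int li = lin.active[a];
      int dest = pick_other_deme_uniform(lin.deme[li], n_demes);
      cnt[lin.deme[li]]--; cnt[dest]++;
      lin.deme[li] = dest;
    } else {
      std::vector<int> here;
      for (size_t a = 0; a < lin.active.size(); ++a)
        if (lin.deme[lin.active[a]] == best_deme) here.push_back((int)a);
      int i1 = (int)std::floor(unif_rand() * here.size());
      int i2 = (int)std::floor(unif_rand() * (here.size() - 1));
      if (i2 >= i1) ++i2;
      lin.coalesce(here[i1], here[i2], t, gen);
      cnt[best_deme]--;
    }
  }
  // phase 2: single ancestral population of constant size
  while (lin.active.size() > 1) {
    size_t k = lin.active.size();
    double lam = k * (k - 1) / 2.0 / (2.0 * ancestral_size);
    t += R::exp_rand() / lam;
    int i1 = (int)std::floor(unif_rand() * k);
    int i2 = (int)std::floor(unif_rand() * (k - 1));
    if (i2 >= i1) ++i2;
    lin.coalesce(i1, i2, t, gen);
  }
  gen.tmrca = t;

  IntegerMatrix counts(n_snps, n_demes);
  for (int s = 0; s < n_snps; ++s) {
    int b = gen.sample_branch();
    for (int leaf : gen.bdesc[b]) counts(s, sample_deme[leaf])++;
  }
  return List::create(_["counts"] = counts,
                      _["tmrca"] = gen.tmrca,
                      _["tree_length"] = gen.total_length());
}
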