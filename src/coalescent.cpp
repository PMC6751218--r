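// Structured-coalescent engine for expected-SFS computation and RAD-locus
// haplotype simulation.
//
// Conventions (documented in ?simulate_expected_sfs):
//  - population sizes are in "2Ne" units (number of gene copies): the
//    pairwise coalescence rate inside a deme of size N is 1/N per generation;
//  - `mig` holds *backward* per-lineage rates: mig(j, i) is the rate at which
//    a lineage currently in deme j jumps (backward in time) into deme i;
//  - events are rows (time, kind, d1, d2, x), sorted by time (backward,
//    generations before present):
//      kind 1  move   all lineages in d1 -> d2; migration to/from d1 zeroed
//              (d1 does not exist before this time, forward in time)
//      kind 2  pulse  each lineage in d1 independently -> d2 with prob x
//      kind 3  setmig backward rate d1 -> d2 set to x
//      kind 4  setsize size of d1 set to x
//  - demes with samples[d] > 0 are "sampled"; the SFS is indexed over these
//    demes only, in deme order, with per-deme allele counts 0..samples[d].
//
// Both entry points draw from R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes them reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct SimConfig {
  int nd;                       // number of demes
  std::vector<double> sizes0;   // sizes at time 0
  std::vector<int> samples;     // haploid samples per deme
  std::vector<double> mig0;     // nd x nd backward rates at time 0 (row-major)
  NumericMatrix events;         // ne x 5, time-sorted
  int nleaf;
  int k;                        // number of sampled demes
  std::vector<int> sampled;     // indices of sampled demes
  std::vector<int> dim;         // samples[sampled[j]] + 1
  std::vector<int> mult;        // index multipliers (first sampled deme fastest)
};

SimConfig make_config(const NumericVector &sizes, const IntegerVector &samples,
                      const NumericMatrix &mig, const NumericMatrix &events) {
  SimConfig cfg;
  cfg.nd = sizes.size();
  if (samples.size() != cfg.nd || mig.nrow() != cfg.nd || mig.ncol() != cfg.nd)
    stop("sizes, samples and mig dimensions disagree");
  cfg.sizes0.assign(sizes.begin(), sizes.end());
  cfg.samples.assign(samples.begin(), samples.end());
  cfg.mig0.resize(cfg.nd * cfg.nd);
  for (int i = 0; i < cfg.nd; ++i)
    for (int j = 0; j < cfg.nd; ++j) cfg.mig0[i * cfg.nd + j] = mig(i, j);
  cfg.events = events;
  cfg.nleaf = 0;
  for (int d = 0; d < cfg.nd; ++d) {
    if (cfg.sizes0[d] <= 0) stop("deme sizes must be positive");
    if (cfg.samples[d] > 0) {
      cfg.sampled.push_back(d);
      cfg.nleaf += cfg.samples[d];
    }
  }
  cfg.k = cfg.sampled.size();
  if (cfg.nleaf < 2) stop("need at least two sampled lineages");
  cfg.dim.resize(cfg.k);
  cfg.mult.resize(cfg.k);
  int m = 1;
  for (int j = 0; j < cfg.k; ++j) {
    cfg.dim[j] = cfg.samples[cfg.sampled[j]] + 1;
    cfg.mult[j] = m;
    m *= cfg.dim[j];
  }
  return cfg;
}

// State of one genealogy simulation; reused across replicates.
struct TreeSim {
  const SimConfig &cfg;
  // per node (0..2n-2): deme at present moment (active only), birth time,
  // per-sampled-deme descendant counts, merge records for mutation dropping
  std::vector<int> dm;
  std::vector<double> birth;
  std::vector<int> cnt;       // node * k + j
  std::vector<int> ch1, ch2;  // children of internal nodes (node id or -1)
  std::vector<double> brl;    // branch length above node (filled at merge)
  std::vector<int> active;    // active node ids
  std::vector<int> kd;        // active lineage count per deme
  std::vector<double> sizes;
  std::vector<double> mig;    // nd x nd row-major
  std::vector<double> outr;   // row sums of mig
  int nnode;

  explicit TreeSim(const SimConfig &c) : cfg(c) {
    int maxn = 2 * cfg.nleaf - 1;
    dm.resize(maxn);
    birth.resize(maxn);
    cnt.resize((size_t)maxn * cfg.k);
    ch1.resize(maxn);
    ch2.resize(maxn);
    brl.resize(maxn);
    kd.resize(cfg.nd);
    sizes.resize(cfg.nd);
    mig.resize(cfg.nd * cfg.nd);
    outr.resize(cfg.nd);
  }

  void refresh_outr(int d) {
    double s = 0;
    for (int i = 0; i < cfg.nd; ++i) s += mig[d * cfg.nd + i];
    outr[d] = s;
  }

  // Simulate one genealogy. If acc is non-null, add branch lengths into the
  // SFS accumulator. Returns total branch length.
  double simulate(double *acc) {
    const int nd = cfg.nd, k = cfg.k;
    sizes = cfg.sizes0;
    mig = cfg.mig0;
    for (int d = 0; d < nd; ++d) refresh_outr(d);
    std::fill(kd.begin(), kd.end(), 0);
    active.clear();
    int node = 0;
    for (int j = 0; j < k; ++j) {
      int d = cfg.sampled[j];
      for (int s = 0; s < cfg.samples[d]; ++s) {
        dm[node] = d;
        birth[node] = 0.0;
        for (int jj = 0; jj < k; ++jj) cnt[(size_t)node * k + jj] = 0;
        cnt[(size_t)node * k + j] = 1;
        ch1[node] = ch2[node] = -1;
        brl[node] = 0.0;
        active.push_back(node);
        kd[d]++;
        node++;
      }
    }
    nnode = node;
    double t = 0.0, total_len = 0.0;
    int iev = 0;
    const int nev = cfg.events.nrow();
    long guard = 0;

    while ((int)active.size() > 1) {
      if (++guard > 100000000L) stop("coalescent simulation did not finish");
      double crate = 0.0, mrate = 0.0;
      for (int d = 0; d < nd; ++d) {
        if (kd[d] > 1) crate += 0.5 * kd[d] * (kd[d] - 1) / sizes[d];
        if (kd[d] > 0) mrate += kd[d] * outr[d];
      }
      double total = crate + mrate;
      double tnext = (total > 0) ? t + exp_rand() / total : R_PosInf;
      if (iev < nev && tnext >= cfg.events(iev, 0)) {
        // apply next demographic event
        t = cfg.events(iev, 0);
        int kind = (int)cfg.events(iev, 1);
        int d1 = (int)cfg.events(iev, 2);
        int d2 = (int)cfg.events(iev, 3);
        double x = cfg.events(iev, 4);
        if (kind == 1) {  // move (population split, backward)
          for (size_t a = 0; a < active.size(); ++a) {
            int nd_ = active[a];
            if (dm[nd_] == d1) { dm[nd_] = d2; kd[d1]--; kd[d2]++; }
          }
          for (int i = 0; i < nd; ++i) {
            mig[d1 * nd + i] = 0.0;
            mig[i * nd + d1] = 0.0;
          }
          for (int i = 0; i < nd; ++i) refresh_outr(i);
        } else if (kind == 2) {  // admixture pulse
          for (size_t a = 0; a < active.size(); ++a) {
            int nd_ = active[a];
            if (dm[nd_] == d1 && unif_rand() < x) {
              dm[nd_] = d2; kd[d1]--; kd[d2]++;
            }
          }
        } else if (kind == 3) {  // set backward migration rate
          mig[d1 * nd + d2] = x;
          refresh_outr(d1);
        } else if (kind == 4) {  // set deme size
          sizes[d1] = x;
        } else stop("unknown event kind");
        iev++;
        continue;
      }
      if (!R_FINITE(tnext))
        stop("remaining lineages can never coalesce (model topology error)");
      t = tnext;
      if (unif_rand() * total < crate) {
        // coalescence: choose deme proportional to rate
        double u = unif_rand() * crate, cum = 0.0;
        int d = -1;
        for (int dd = 0; dd < nd; ++dd) {
          if (kd[dd] > 1) {
            cum += 0.5 * kd[dd] * (kd[dd] - 1) / sizes[dd];
            if (u <= cum) { d = dd; break; }
          }
        }
        if (d < 0) d = nd - 1;
        // choose an unordered pair of active lineages in deme d
        int i1 = (int)(unif_rand() * kd[d]), i2 = (int)(unif_rand() * (kd[d] - 1));
        if (i2 >= i1) i2++;
        int a1 = -1, a2 = -1, seen = 0;
        for (size_t a = 0; a < active.size(); ++a) {
          if (dm[active[a]] == d) {
            if (seen == i1) a1 = (int)a;
            if (seen == i2) a2 = (int)a;
            seen++;
          }
        }
        int n1 = active[a1], n2 = active[a2];
        // record branches of the two children
        for (int c = 0; c < 2; ++c) {
          int nc = c == 0 ? n1 : n2;
          double len = t - birth[nc];
          brl[nc] = len;
          total_len += len;
          if (acc) {
            int idx = 0;
            for (int j = 0; j < k; ++j) idx += cnt[(size_t)nc * k + j] * cfg.mult[j];
            acc[idx] += len;
          }
        }
        int p = nnode++;
        dm[p] = d;
        birth[p] = t;
        ch1[p] = n1; ch2[p] = n2;
        brl[p] = 0.0;
        for (int j = 0; j < k; ++j)
          cnt[(size_t)p * k + j] = cnt[(size_t)n1 * k + j] + cnt[(size_t)n2 * k + j];
        // replace n1 by parent, remove n2 (swap with last)
        active[a1] = p;
        active[a2] = active.back();
        active.pop_back();
        kd[d]--;
      } else {
        // migration: choose lineage proportional to its deme's out-rate
        double u = unif_rand() * mrate, cum = 0.0;
        int chosen = -1;
        for (size_t a = 0; a < active.size(); ++a) {
          cum += outr[dm[active[a]]];
          if (u <= cum) { chosen = (int)a; break; }
        }
        if (chosen < 0) chosen = (int)active.size() - 1;
        int nd_ = active[chosen];
        int d = dm[nd_];
        double u2 = unif_rand() * outr[d], cum2 = 0.0;
        int dest = -1;
        for (int i = 0; i < cfg.nd; ++i) {
          cum2 += mig[d * cfg.nd + i];
          if (u2 <= cum2) { dest = i; break; }
        }
        if (dest < 0) continue;
        dm[nd_] = dest;
        kd[d]--; kd[dest]++;
      }
    }
    return total_len;
  }

  // collect leaves below `node` into out (0/1 per leaf id)
  void subtree_leaves(int node, std::vector<int> &out) const {
    std::vector<int> stack{node};
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (ch1[v] < 0) out[v] = 1;
      else { stack.push_back(ch1[v]); stack.push_back(ch2[v]); }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector coal_branch_sfs(NumericVector sizes, IntegerVector samples,
                              NumericMatrix mig, NumericMatrix events,
                              int n_sims) {
  SimConfig cfg = make_config(sizes, samples, mig, events);
  int ncell = 1;
  for (int j = 0; j < cfg.k; ++j) ncell *= cfg.dim[j];
  NumericVector acc(ncell);
  TreeSim sim(cfg);
  for (int r = 0; r < n_sims; ++r) {
    sim.simulate(REAL(acc));
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < ncell; ++i) acc[i] /= n_sims;
  return acc;  // mean branch length subtending each count configuration
}

// [[Rcpp::export]]
List coal_locus_mutations(NumericVector sizes, IntegerVector samples,
                          NumericMatrix mig, NumericMatrix events,
                          int n_loci, double locus_theta) {
  SimConfig cfg = make_config(sizes, samples, mig, events);
  TreeSim sim(cfg);
  std::vector<int> carriers;  // flattened rows of length nleaf
  std::vector<int> locus_of;
  std::vector<int> row(cfg.nleaf);
  for (int l = 0; l < n_loci; ++l) {
    double total_len = sim.simulate(nullptr);
    int nmut = (int)R::rpois(total_len * locus_theta);
    if (nmut == 0) continue;
    // branch sampling: cumulative branch lengths over non-root nodes
    int nn = sim.nnode;
    std::vector<double> cum(nn);
    double c = 0.0;
    for (int v = 0; v < nn; ++v) { c += sim.brl[v]; cum[v] = c; }
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * total_len;
      int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (v >= nn) v = nn - 1;
      std::fill(row.begin(), row.end(), 0);
      sim.subtree_leaves(v, row);
      carriers.insert(carriers.end(), row.begin(), row.end());
      locus_of.push_back(l + 1);
    }
    Rcpp::checkUserInterrupt();
  }
  int nmut_total = locus_of.size();
  IntegerMatrix cm(nmut_total, cfg.nleaf);
  for (int i = 0; i < nmut_total; ++i)
    for (int j = 0; j < cfg.nleaf; ++j) cm(i, j) = carriers[(size_t)i * cfg.nleaf + j];
  return List::create(_["carriers"] = cm,
                      _["locus"] = IntegerVector(locus_of.begin(), locus_of.end()));
}
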