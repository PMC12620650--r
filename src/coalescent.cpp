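// Single-locus structured coalescent under a piecewise-constant demographic
// model: population divergences (backward-time lineage moves), size changes
// (bottlenecks are a pair of size events), continuous backward migration and
// admixture pulses.  Drives both the Monte-Carlo expected SFS used by the
// composite-likelihood machinery and the genotype-panel simulator.
//
// Conventions: time in generations, measured backward from 0 (present);
// sizes are diploid N_e, so a pair of lineages in a population of size N
// coalesces at rate 1/(2N); events are pre-sorted by time.

#include <Rcpp.h>
#include <random>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Branch {
  int cell;
  uint64_t mask;
  double len;
};

// event types
constexpr int EV_MERGE = 0;  // lineages in pop a move to pop b (divergence)
constexpr int EV_SIZE  = 1;  // pop a size set to x
constexpr int EV_MIG   = 2;  // backward migration rate a -> b set to x
constexpr int EV_PULSE = 3;  // each lineage in a moves to b with prob x

class CoalSim {
public:
  CoalSim(int n_pops, const IntegerVector& samp,
          const NumericVector& init_sizes, const NumericMatrix& events,
          uint64_t seed)
    : np_(n_pops), rng_(seed), unif_(0.0, 1.0) {
    samp_.assign(samp.begin(), samp.end());
    sizes0_.assign(init_sizes.begin(), init_sizes.end());
    n_ev_ = events.nrow();
    ev_.resize(n_ev_ * 5);
    for (int i = 0; i < n_ev_; ++i)
      for (int j = 0; j < 5; ++j) ev_[i * 5 + j] = events(i, j);
    n_leaves_ = 0;
    strides_.resize(np_);
    int s = 1;
    for (int p = 0; p < np_; ++p) {
      strides_[p] = (samp_[p] > 0) ? s : 0;
      if (samp_[p] > 0) s *= samp_[p] + 1;
      n_leaves_ += samp_[p];
    }
    n_cells_ = s;
    if (n_leaves_ > 64) stop("at most 64 sampled haploids supported");
    int maxlin = 2 * n_leaves_ + 2;
    pop_.resize(maxlin); cell_.resize(maxlin); mask_.resize(maxlin);
    birth_.resize(maxlin);
    bypop_.resize(np_);
    for (int p = 0; p < np_; ++p) bypop_[p].reserve(n_leaves_);
    N_.resize(np_); mig_.resize(np_ * np_); migrow_.resize(np_);
    crate_.resize(np_); mrate_.resize(np_); inv4N_.resize(np_);
  }

  int n_cells() const { return n_cells_; }
  int n_leaves() const { return n_leaves_; }

  // re-seed the generator for one genealogy: with a per-tree stream,
  // evaluations at nearby parameter values stay coupled tree by tree
  // (common random numbers), instead of decoupling after the first
  // path divergence
  void seed_tree(uint64_t base, long tree) {
    rng_.seed(base + 0x9e3779b97f4a7c15ULL * (uint64_t)(tree + 1));
  }

  // simulate one genealogy; append branches (cell, mask, length)
  double simulate(std::vector<Branch>& out) {
    for (int p = 0; p < np_; ++p) { N_[p] = sizes0_[p]; bypop_[p].clear(); }
    std::fill(mig_.begin(), mig_.end(), 0.0);
    std::fill(migrow_.begin(), migrow_.end(), 0.0);
    int nl = 0, leaf = 0;
    for (int p = 0; p < np_; ++p)
      for (int i = 0; i < samp_[p]; ++i) {
        pop_[nl] = p; cell_[nl] = strides_[p];
        mask_[nl] = (uint64_t)1 << leaf; birth_[nl] = 0.0;
        bypop_[p].push_back(nl);
        ++nl; ++leaf;
      }
    double t = 0.0, ttot = 0.0;
    int n_active = n_leaves_;
    int iev = 0;
    for (int p = 0; p < np_; ++p) inv4N_[p] = 0.25 / N_[p];
    refresh_rates();
    while (n_active > 1) {
      double R = R_;
      double t_next = (iev < n_ev_) ? ev_[iev * 5] : R_PosInf;
      if (R <= 0.0) {
        if (iev >= n_ev_)
          stop("genealogy cannot coalesce: populations never merge");
        t = t_next;
        apply_event(iev++, t, nl);
        refresh_rates();
        continue;
      }
      double dt = -std::log(1.0 - unif_(rng_)) / R;
      if (t + dt >= t_next) {
        t = t_next;
        apply_event(iev++, t, nl);
        refresh_rates();
        continue;
      }
      t += dt;
      double u = unif_(rng_) * R;
      int p = 0;
      for (; p < np_ - 1; ++p) {
        if (u < crate_[p] + mrate_[p]) break;
        u -= crate_[p] + mrate_[p];
      }
      std::vector<int>& v = bypop_[p];
      int k = (int)v.size();
      if (u < crate_[p]) {
        // coalescence in p: pick two distinct lineages
        int i = (int)(unif_(rng_) * k); if (i >= k) i = k - 1;
        int j = (int)(unif_(rng_) * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int li = v[i], lj = v[j];
        Branch b1 = {cell_[li], mask_[li], t - birth_[li]};
        Branch b2 = {cell_[lj], mask_[lj], t - birth_[lj]};
        out.push_back(b1); out.push_back(b2);
        ttot += b1.len + b2.len;
        cell_[li] += cell_[lj];
        mask_[li] |= mask_[lj];
        birth_[li] = t;
        v[j] = v.back(); v.pop_back();  // drop lj; li stays active
        --n_active;
        update_pop_rate(p);
      } else {
        // migration of one lineage out of p
        u -= crate_[p];
        int q = 0; double uu = u / k;
        for (; q < np_ - 1; ++q) { if (uu < mig_[p * np_ + q]) break; uu -= mig_[p * np_ + q]; }
        int i = (int)(unif_(rng_) * k); if (i >= k) i = k - 1;
        int li = v[i];
        v[i] = v.back(); v.pop_back();
        pop_[li] = q;
        bypop_[q].push_back(li);
        update_pop_rate(p);
        update_pop_rate(q);
      }
    }
    return ttot;
  }

private:
  void apply_event(int iev, double t, int nl) {
    (void)t; (void)nl;
    int type = (int)ev_[iev * 5 + 1];
    int a = (int)ev_[iev * 5 + 2], b = (int)ev_[iev * 5 + 3];
    double x = ev_[iev * 5 + 4];
    if (type == EV_MERGE) {
      for (size_t z = 0; z < bypop_[a].size(); ++z) {
        int li = bypop_[a][z];
        pop_[li] = b;
        bypop_[b].push_back(li);
      }
      bypop_[a].clear();
      for (int q = 0; q < np_; ++q) { mig_[a * np_ + q] = 0.0; mig_[q * np_ + a] = 0.0; }
      refresh_migrow();
    } else if (type == EV_SIZE) {
      N_[a] = x;
      inv4N_[a] = 0.25 / x;
    } else if (type == EV_MIG) {
      mig_[a * np_ + b] = x;
      refresh_migrow();
    } else if (type == EV_PULSE) {
      scratch_.clear();
      for (size_t z = 0; z < bypop_[a].size(); ++z) {
        int li = bypop_[a][z];
        if (unif_(rng_) < x) { pop_[li] = b; bypop_[b].push_back(li); }
        else scratch_.push_back(li);
      }
      bypop_[a].swap(scratch_);
    }
  }

  void update_pop_rate(int p) {
    R_ -= crate_[p] + mrate_[p];
    int k = (int)bypop_[p].size();
    crate_[p] = (k > 1) ? k * (k - 1) * inv4N_[p] : 0.0;
    mrate_[p] = k * migrow_[p];
    R_ += crate_[p] + mrate_[p];
  }

  void refresh_rates() {
    R_ = 0.0;
    for (int p = 0; p < np_; ++p) {
      int k = (int)bypop_[p].size();
      crate_[p] = (k > 1) ? k * (k - 1) * inv4N_[p] : 0.0;
      mrate_[p] = k * migrow_[p];
      R_ += crate_[p] + mrate_[p];
    }
  }

  void refresh_migrow() {
    for (int p = 0; p < np_; ++p) {
      double s = 0.0;
      for (int q = 0; q < np_; ++q) s += mig_[p * np_ + q];
      migrow_[p] = s;
    }
  }

  int np_, n_cells_, n_leaves_, n_ev_;
  std::vector<int> samp_, strides_;
  std::vector<double> sizes0_, ev_;
  // per-replicate buffers, reused across simulations
  std::vector<int> pop_, cell_;
  std::vector<uint64_t> mask_;
  std::vector<double> birth_, N_, mig_, migrow_, crate_, mrate_, inv4N_;
  double R_;
  std::vector<std::vector<int> > bypop_;
  std::vector<int> scratch_;
  std::mt19937_64 rng_;
  std::uniform_real_distribution<double> unif_;
};

}  // namespace

// Monte-Carlo expected branch lengths per joint-SFS cell.
// Returns: list(cell_len = mean branch length subtending each derived-count
// combination (flattened, strides over sampled pops in order), total_len =
// mean total tree length, n_cells, n_reps).
// [[Rcpp::export]]
List sim_expected_sfs_cpp(int n_pops, IntegerVector sample_sizes,
                          NumericVector init_sizes, NumericMatrix events,
                          int n_reps, double seed) {
  CoalSim sim(n_pops, sample_sizes, init_sizes, events, (uint64_t)seed);
  std::vector<double> cell(sim.n_cells(), 0.0);
  double tot = 0.0;
  std::vector<Branch> br;
  br.reserve(2 * sim.n_leaves());
  for (int r = 0; r < n_reps; ++r) {
    sim.seed_tree((uint64_t)seed, r);
    br.clear();
    tot += sim.simulate(br);
    for (size_t i = 0; i < br.size(); ++i) cell[br[i].cell] += br[i].len;
  }
  NumericVector out(cell.begin(), cell.end());
  for (int i = 0; i < out.size(); ++i) out[i] /= n_reps;
  return List::create(_["cell_len"] = out, _["total_len"] = tot / n_reps,
                      _["n_cells"] = sim.n_cells(), _["n_reps"] = n_reps);
}

// Simulate segregating sites: each genealogy represents one locus of
// bp_per_locus base pairs; mutation count per locus ~ Poisson(mu * bp * T);
// each mutation lands on a branch with probability proportional to length.
// Returns derived-allele carrier matrix (haploids x sites, 0/1), the locus
// index of each site and its uniform within-locus offset.
// [[Rcpp::export]]
List sim_sites_cpp(int n_pops, IntegerVector sample_sizes,
                   NumericVector init_sizes, NumericMatrix events,
                   int n_loci, double bp_per_locus, double mu, double seed) {
  CoalSim sim(n_pops, sample_sizes, init_sizes, events, (uint64_t)seed);
  int nl = sim.n_leaves();
  std::mt19937_64 mrng((uint64_t)seed ^ 0x9e3779b97f4a7c15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<uint64_t> masks;
  std::vector<int> locus;
  std::vector<double> offset;
  std::vector<Branch> br;
  br.reserve(2 * nl);
  for (int r = 0; r < n_loci; ++r) {
    sim.seed_tree((uint64_t)seed, r);
    br.clear();
    double ttot = sim.simulate(br);
    double lam = mu * bp_per_locus * ttot;
    int nmut = 0;
    if (lam > 0) {
      std::poisson_distribution<int> pois(lam);
      nmut = pois(mrng);
    }
    for (int m = 0; m < nmut; ++m) {
      double u = unif(mrng) * ttot;
      size_t bi = 0;
      for (; bi + 1 < br.size(); ++bi) {
        if (u < br[bi].len) break;
        u -= br[bi].len;
      }
      masks.push_back(br[bi].mask);
      locus.push_back(r + 1);
      offset.push_back(unif(mrng));
    }
  }
  int S = (int)masks.size();
  IntegerMatrix G(nl, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < nl; ++i)
      G(i, s) = (masks[s] >> i) & 1;
  return List::create(_["carriers"] = G,
                      _["locus"] = IntegerVector(locus.begin(), locus.end()),
                      _["offset"] = NumericVector(offset.begin(), offset.end()));
}

// Monte-Carlo expected branch lengths restricted to a set of cells
// (0-based linear indices) plus the grand total: the compact evaluation
// path used by the composite-likelihood optimizer on large joint spectra.
// [[Rcpp::export]]
List sim_expected_cells_cpp(int n_pops, IntegerVector sample_sizes,
                            NumericVector init_sizes, NumericMatrix events,
                            int n_reps, double seed, IntegerVector cells) {
  CoalSim sim(n_pops, sample_sizes, init_sizes, events, (uint64_t)seed);
  std::vector<double> cell(sim.n_cells(), 0.0);
  double tot = 0.0;
  std::vector<Branch> br;
  br.reserve(2 * sim.n_leaves());
  for (int r = 0; r < n_reps; ++r) {
    sim.seed_tree((uint64_t)seed, r);
    br.clear();
    tot += sim.simulate(br);
    for (size_t i = 0; i < br.size(); ++i) cell[br[i].cell] += br[i].len;
  }
  NumericVector out(cells.size());
  for (int i = 0; i < cells.size(); ++i)
    out[i] = cell[cells[i]] / n_reps;
  return List::create(_["cell_len"] = out, _["total_len"] = tot / n_reps);
}
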