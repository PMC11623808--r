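// Monte-Carlo core for the discrete-time Moran Birth-death process with
// global resource-competition fitness.
//
// Well-mixed-resource mode: fitness depends on the total mutant count only,
// so sampling a reproducer is a two-class draw (mutant class weight n*f(n),
// wild-type class weight N-n) followed by a uniform pick inside the class.
//
// Diffusible-resource mode: per-resource steady states solve
// (D*L + diag(alpha_i)) c_i = S. Occupancy changes at one node per
// replacement event, so the inverse of each system matrix is maintained by
// Sherman-Morrison rank-1 updates, with a periodic full re-factorization to
// keep the drift below solver precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ with Lemire bounded sampling: fast, and its streams do not
// depend on the standard library implementation
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int bounded(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
};

// per-replicate RNG stream: counter-based spawn from the master seed, so
// replicate r gets the same stream regardless of batching
static inline Rng replicate_rng(uint64_t master, uint64_t rep) {
  return Rng(master ^ (0x9E3779B97F4A7C15ULL * (rep + 1)));
}

struct Occupancy {
  int N, n_mut;
  std::vector<uint8_t> is_mut;
  std::vector<int> mlist, wlist; // node ids per class
  std::vector<int> where;        // position of node in its class list

  void reset(int N_) {
    N = N_; n_mut = 0;
    is_mut.assign(N, 0);
    mlist.clear();
    wlist.resize(N);
    where.resize(N);
    for (int v = 0; v < N; ++v) { wlist[v] = v; where[v] = v; }
  }
  void flip(int v) {
    if (is_mut[v]) { // mut -> wt
      int pos = where[v], last = mlist.back();
      mlist[pos] = last; where[last] = pos; mlist.pop_back();
      where[v] = (int)wlist.size(); wlist.push_back(v);
      is_mut[v] = 0; --n_mut;
    } else {         // wt -> mut
      int pos = where[v], last = wlist.back();
      wlist[pos] = last; where[last] = pos; wlist.pop_back();
      where[v] = (int)mlist.size(); mlist.push_back(v);
      is_mut[v] = 1; ++n_mut;
    }
  }
};

// [[Rcpp::export]]
List sim_wellmixed_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                       NumericVector fmut, int n_reps, double master_seed,
                       int est_threshold, double max_steps,
                       IntegerVector start_nodes) {
  const int N = adj_ptr.size() - 1;
  IntegerVector outcome(n_reps);
  NumericVector steps_out(n_reps), est_step(n_reps);
  LogicalVector established(n_reps);
  Occupancy occ;

  for (int rep = 0; rep < n_reps; ++rep) {
    Rng rng = replicate_rng((uint64_t)master_seed, (uint64_t)rep);
    occ.reset(N);
    int start = start_nodes[rep % start_nodes.size()];
    if (start < 0) start = rng.bounded(N);
    occ.flip(start);
    double steps = 0.0;
    bool est = false;
    double est_at = NA_REAL;
    if (est_threshold > 0 && occ.n_mut >= est_threshold) { est = true; est_at = 0; }
    int out = NA_INTEGER;
    while (true) {
      if (occ.n_mut == 0) { out = 0; break; }
      if (occ.n_mut == N) { out = 1; break; }
      if (steps >= max_steps) { out = NA_INTEGER; break; }
      const int n = occ.n_mut;
      const double r = fmut[n];
      const double Wm = n * r, W = Wm + (N - n);
      int parent;
      if (rng.unif() * W < Wm) parent = occ.mlist[rng.bounded(n)];
      else                    parent = occ.wlist[rng.bounded(N - n)];
      const int d0 = adj_ptr[parent], deg = adj_ptr[parent + 1] - d0;
      const int tgt = adj_idx[d0 + rng.bounded(deg)];
      steps += 1.0;
      if (occ.is_mut[tgt] != occ.is_mut[parent]) {
        occ.flip(tgt);
        if (est_threshold > 0 && !est && occ.n_mut >= est_threshold) {
          est = true; est_at = steps;
        }
      }
    }
    outcome[rep] = out;
    steps_out[rep] = steps;
    established[rep] = est;
    est_step[rep] = est_at;
    if ((rep & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps_out,
                      _["established"] = established,
                      _["establishment_step"] = est_step);
}

struct ResourceField {
  arma::mat Minv[2];
  arma::vec c[2];
  arma::vec alpha_node[2]; // current per-node consumption per resource
  const arma::mat *DL;     // D * Laplacian
  double supply;
  double a_wt[2], a_mut[2];
  int flips_since_refresh, refresh_every;

  void full_refresh(const Occupancy &occ) {
    const int N = occ.N;
    for (int i = 0; i < 2; ++i) {
      arma::mat M = *DL;
      for (int v = 0; v < N; ++v) {
        double a = occ.is_mut[v] ? a_mut[i] : a_wt[i];
        alpha_node[i][v] = a;
        M(v, v) += a;
      }
      Minv[i] = arma::inv_sympd(M);
      c[i] = Minv[i] * arma::vec(N, arma::fill::value(supply));
    }
    flips_since_refresh = 0;
  }

  // node v has just flipped in `occ`; update inverses and concentrations
  void rank1_update(const Occupancy &occ, int v) {
    if (++flips_since_refresh >= refresh_every) { full_refresh(occ); return; }
    for (int i = 0; i < 2; ++i) {
      double a_new = occ.is_mut[v] ? a_mut[i] : a_wt[i];
      double delta = a_new - alpha_node[i][v];
      alpha_node[i][v] = a_new;
      arma::vec g = Minv[i].col(v);
      double denom = 1.0 + delta * g[v];
      c[i] -= (delta * c[i][v] / denom) * g;
      Minv[i] -= (delta / denom) * (g * g.t());
    }
  }
};

// [[Rcpp::export]]
List sim_diffusible_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                        NumericMatrix laplacian,
                        NumericVector alpha_wt, NumericVector alpha_mut,
                        double s_mut, double D, double supply,
                        int n_reps, double master_seed, int est_threshold,
                        double max_steps, IntegerVector start_nodes,
                        int refresh_every) {
  const int N = adj_ptr.size() - 1;
  IntegerVector outcome(n_reps);
  NumericVector steps_out(n_reps), est_step(n_reps);
  LogicalVector established(n_reps);

  arma::mat DL = D * arma::mat(laplacian.begin(), N, N, false);
  ResourceField rf;
  rf.DL = &DL;
  rf.supply = supply;
  for (int i = 0; i < 2; ++i) {
    rf.a_wt[i] = alpha_wt[i];
    rf.a_mut[i] = alpha_mut[i];
    rf.alpha_node[i].set_size(N);
  }
  rf.refresh_every = refresh_every;

  // all-wild-type baseline, copied at the start of every replicate
  Occupancy occ0; occ0.reset(N);
  rf.full_refresh(occ0);
  arma::mat base_inv[2] = {rf.Minv[0], rf.Minv[1]};
  arma::vec base_c[2] = {rf.c[0], rf.c[1]};
  arma::vec base_alpha[2] = {rf.alpha_node[0], rf.alpha_node[1]};

  Occupancy occ;
  std::vector<double> cumw(N);

  auto rebuild_weights = [&](void) {
    double acc = 0.0;
    for (int v = 0; v < N; ++v) {
      double eco = rf.alpha_node[0][v] * rf.c[0][v] +
                   rf.alpha_node[1][v] * rf.c[1][v];
      double f = (occ.is_mut[v] ? s_mut : 1.0) * eco;
      acc += f;
      cumw[v] = acc;
    }
  };

  for (int rep = 0; rep < n_reps; ++rep) {
    Rng rng = replicate_rng((uint64_t)master_seed, (uint64_t)rep);
    occ.reset(N);
    for (int i = 0; i < 2; ++i) {
      rf.Minv[i] = base_inv[i];
      rf.c[i] = base_c[i];
      rf.alpha_node[i] = base_alpha[i];
    }
    rf.flips_since_refresh = 0;
    int start = start_nodes[rep % start_nodes.size()];
    if (start < 0) start = rng.bounded(N);
    occ.flip(start);
    rf.rank1_update(occ, start);
    rebuild_weights();

    double steps = 0.0;
    bool est = false;
    double est_at = NA_REAL;
    if (est_threshold > 0 && occ.n_mut >= est_threshold) { est = true; est_at = 0; }
    int out = NA_INTEGER;
    while (true) {
      if (occ.n_mut == 0) { out = 0; break; }
      if (occ.n_mut == N) { out = 1; break; }
      if (steps >= max_steps) { out = NA_INTEGER; break; }
      const double W = cumw[N - 1];
      const double u = rng.unif() * W;
      int parent = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                         cumw.begin());
      if (parent >= N) parent = N - 1;
      const int d0 = adj_ptr[parent], deg = adj_ptr[parent + 1] - d0;
      const int tgt = adj_idx[d0 + rng.bounded(deg)];
      steps += 1.0;
      if (occ.is_mut[tgt] != occ.is_mut[parent]) {
        occ.flip(tgt);
        if (occ.n_mut == 0 || occ.n_mut == N) {
          out = (occ.n_mut == N) ? 1 : 0;
          if (est_threshold > 0 && !est && occ.n_mut >= est_threshold) {
            est = true; est_at = steps;
          }
          break;
        }
        rf.rank1_update(occ, tgt);
        rebuild_weights();
        if (est_threshold > 0 && !est && occ.n_mut >= est_threshold) {
          est = true; est_at = steps;
        }
      }
    }
    outcome[rep] = out;
    steps_out[rep] = steps;
    established[rep] = est;
    est_step[rep] = est_at;
    if ((rep & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps_out,
                      _["established"] = established,
                      _["establishment_step"] = est_step);
}
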