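#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Counter-free splitmix64 stream: small state, excellent equidistribution at
// the draw volumes used here, and bit-identical across platforms (no reliance
// on std:: distribution implementations).
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t s) : state(s) {}
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double rexp() { return -std::log(1.0 - u01()); }
  // uniform integer in [0, n); n is tiny (sample sizes), modulo bias ~ n/2^64
  int runif_int(int n) { return (int)(next() % (uint64_t)n); }
};

// Deterministic replicate sub-stream: all draws of replicate `rep` under user
// seed `seed` come from this state, so batch runs and single-tree runs agree.
static uint64_t rep_state(int seed, int rep) {
  uint64_t x = (uint64_t)(uint32_t)seed;
  x = x * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL;
  x ^= ((uint64_t)(uint32_t)rep + 1ULL) * 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 33;
  return x;
}

struct Deme {
  double size;  // reference diploid effective size at tref
  double r;     // forward-time exponential growth rate per generation
  double tref;  // backward time at which `size` is the size
  bool active;
};

// backward-time size: N(t) = size * exp(-r * (t - tref))
static double deme_size_at(const Deme &d, double t) {
  if (d.r == 0.0) return d.size;
  return d.size * std::exp(-d.r * (t - d.tref));
}

struct Lin {
  int deme;
  int node;      // 0-based node id at the bottom of this branch
  double birth;  // time of that node
  int c0, c1;    // subtended leaf counts per SFS group
};

struct Ev {
  double time;
  int kind;  // 1 resize, 2 set_growth, 3 set_migration, 4 mass_move
  int d1, d2;
  double value;
};

struct DemModel {
  int n_demes;
  std::vector<Deme> demes0;
  std::vector<double> mig0;  // row-major n_demes x n_demes
  std::vector<Ev> events;
  double max_time;
};

static DemModel parse_dem(const List &dem) {
  DemModel M;
  NumericVector size = dem["size"];
  NumericVector growth = dem["growth"];
  NumericMatrix mig = dem["mig"];
  M.n_demes = size.size();
  M.demes0.resize(M.n_demes);
  for (int i = 0; i < M.n_demes; ++i)
    M.demes0[i] = Deme{size[i], growth[i], 0.0, true};
  M.mig0.assign(M.n_demes * M.n_demes, 0.0);
  for (int i = 0; i < M.n_demes; ++i)
    for (int j = 0; j < M.n_demes; ++j)
      if (i != j) M.mig0[i * M.n_demes + j] = mig(i, j);
  NumericVector et = dem["ev_time"];
  IntegerVector ek = dem["ev_kind"], e1 = dem["ev_d1"], e2 = dem["ev_d2"];
  NumericVector ev = dem["ev_value"];
  for (int i = 0; i < et.size(); ++i)
    M.events.push_back(Ev{et[i], ek[i], e1[i], e2[i], ev[i]});
  M.max_time = as<double>(dem["max_time"]);
  return M;
}

// One structured-coalescent realization. Fills tree arrays when build_tree,
// and/or accumulates per-branch length into sfs (dims (n1+1) x (n2+1),
// column-major, indexed by group leaf counts) when sfs != nullptr.
//
// SFS accrual is per state interval: every living lineage's frequency class
// receives the interval duration. With rao_blackwell, the realized duration
// of an interval ending in a coalescence/migration is replaced by its
// conditional expectation given the branch taken (exact while every deme
// holding >= 2 lineages has zero growth, since then the time to the next
// event is exponential and independent of the event type); this removes the
// waiting-time noise from the Monte-Carlo expected SFS without biasing it.
// State evolution always uses the realized times.
// levelP, when non-null, holds the single-population branch-size law
// P(a branch among k ancestral lineages subtends i of the n leaves) =
// C(n-i-1, k-2) / C(n-1, k-1), laid out as levelP[k * (n+1) + i]. It lets a
// single-deme run accrue the exact expected class composition per level
// (valid only when all lineages are exchangeable, i.e. one deme).
static void simulate_one(const DemModel &M, const IntegerVector &samp,
                         const std::vector<int> &grp, Rng &rng, bool build_tree,
                         std::vector<int> *parent, std::vector<double> *ntime,
                         std::vector<int> *leaf_deme, double *sfs, int dim1,
                         bool rao_blackwell = false,
                         const std::vector<double> *levelP = nullptr,
                         int n_total = 0) {
  const int nd = M.n_demes;
  std::vector<Deme> demes = M.demes0;
  std::vector<double> mig = M.mig0;
  std::vector<double> outm(nd, 0.0);
  auto recompute_outm = [&]() {
    for (int i = 0; i < nd; ++i) {
      double s = 0.0;
      for (int j = 0; j < nd; ++j) s += mig[i * nd + j];
      outm[i] = s;
    }
  };
  recompute_outm();

  int n = 0;
  for (int d = 0; d < nd; ++d) n += samp[d];
  std::vector<Lin> lin;
  lin.reserve(n);
  int node = 0;
  for (int d = 0; d < nd; ++d)
    for (int k = 0; k < samp[d]; ++k) {
      lin.push_back(Lin{d, node, 0.0, grp[d] == 0 ? 1 : 0, grp[d] == 1 ? 1 : 0});
      if (build_tree) (*leaf_deme)[node] = d;
      ++node;
    }
  if (build_tree) {
    parent->assign(2 * n - 1, -1);
    ntime->assign(2 * n - 1, 0.0);
  }
  int next_node = n;
  double t = 0.0;
  size_t ev = 0;
  std::vector<int> kd(nd, 0);

  while ((int)lin.size() > 1) {
    double t_ev = ev < M.events.size() ? M.events[ev].time : INF;
    std::fill(kd.begin(), kd.end(), 0);
    for (size_t i = 0; i < lin.size(); ++i) kd[lin[i].deme]++;

    double best_s = INF;
    int best_kind = -1, best_deme = -1;
    bool rb_ok = rao_blackwell;
    double lambda_tot = 0.0;
    for (int d = 0; d < nd; ++d) {
      if (kd[d] < 2) continue;
      double pairs = 0.5 * kd[d] * (kd[d] - 1.0);
      double E = rng.rexp();
      const Deme &D = demes[d];
      if (D.r != 0.0) rb_ok = false;
      else lambda_tot += pairs / (2.0 * D.size);
      double s;
      if (D.r == 0.0) {
        s = E * 2.0 * D.size / pairs;
      } else {
        // invert the cumulative coalescent hazard through the growth phase
        double a0 = t - D.tref;
        double arg = 1.0 + E * D.r * (2.0 * D.size / pairs) * std::exp(-D.r * a0);
        s = (arg <= 0.0) ? INF : std::log(arg) / D.r;
      }
      if (s < best_s) { best_s = s; best_kind = 0; best_deme = d; }
    }
    double Mtot = 0.0;
    for (size_t i = 0; i < lin.size(); ++i) Mtot += outm[lin[i].deme];
    if (Mtot > 0.0) {
      double s = rng.rexp() / Mtot;
      if (s < best_s) { best_s = s; best_kind = 1; }
    }
    lambda_tot += Mtot;

    // accrue interval duration to every living lineage's frequency class
    // (or, single-deme case, to the exact expected class composition)
    auto accrue = [&](double dt) {
      if (!sfs || dt <= 0.0) return;
      if (levelP) {
        int k = (int)lin.size();
        const double *P = levelP->data() + (size_t)k * (n_total + 1);
        int imax = n_total - k + 1;
        for (int i = 1; i <= imax; ++i) sfs[i] += dt * k * P[i];
      } else {
        for (size_t i = 0; i < lin.size(); ++i)
          sfs[lin[i].c0 + (size_t)lin[i].c1 * dim1] += dt;
      }
    };

    if (ev < M.events.size() && t + best_s >= t_ev) {
      accrue(t_ev - t);
      t = t_ev;
      bool mig_changed = false;
      while (ev < M.events.size() && M.events[ev].time == t_ev) {
        const Ev &E = M.events[ev];
        switch (E.kind) {
        case 1:  // resize: new reference size now; growth rate unchanged
          demes[E.d1].size = E.value;
          demes[E.d1].tref = t;
          break;
        case 2:  // set_growth: re-anchor at current size, change rate
          demes[E.d1].size = deme_size_at(demes[E.d1], t);
          demes[E.d1].tref = t;
          demes[E.d1].r = E.value;
          break;
        case 3:  // symmetric migration rate change
          mig[E.d1 * nd + E.d2] = E.value;
          mig[E.d2 * nd + E.d1] = E.value;
          mig_changed = true;
          break;
        case 4:  // mass_move: each lineage in d1 moves to d2 w.p. value
          for (size_t i = 0; i < lin.size(); ++i)
            if (lin[i].deme == E.d1 &&
                (E.value >= 1.0 || rng.u01() < E.value))
              lin[i].deme = E.d2;
          if (E.value >= 1.0) {
            demes[E.d1].active = false;
            for (int j = 0; j < nd; ++j) {
              mig[E.d1 * nd + j] = 0.0;
              mig[j * nd + E.d1] = 0.0;
            }
            mig_changed = true;
          }
          break;
        }
        ++ev;
      }
      if (mig_changed) recompute_outm();
      continue;
    }

    if (!std::isfinite(best_s))
      stop("cannot coalesce: %d lineages remain in isolated demes with no "
           "migration or merge events", (int)lin.size());
    if (rb_ok && lambda_tot > 0.0) {
      // E[S | S < tau] for S ~ Exp(lambda), tau the time to the next
      // demographic event (tau = Inf when none remains)
      double tau = t_ev - t;
      double d_acc;
      if (!std::isfinite(tau)) d_acc = 1.0 / lambda_tot;
      else {
        double q = std::exp(-lambda_tot * tau);
        d_acc = 1.0 / lambda_tot - tau * q / (1.0 - q);
      }
      accrue(d_acc);
    } else {
      accrue(best_s);
    }
    t += best_s;
    if (t > M.max_time)
      stop("cannot coalesce: %d lineages remain at max_time = %g generations",
           (int)lin.size(), M.max_time);

    if (best_kind == 0) {
      int k = kd[best_deme];
      int a = rng.runif_int(k);
      int b = rng.runif_int(k - 1);
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t i = 0; i < lin.size(); ++i) {
        if (lin[i].deme != best_deme) continue;
        if (seen == a) ia = (int)i;
        if (seen == b) ib = (int)i;
        ++seen;
      }
      Lin &A = lin[ia], &B = lin[ib];
      if (build_tree) {
        (*parent)[A.node] = next_node;
        (*parent)[B.node] = next_node;
        (*ntime)[next_node] = t;
      }
      Lin merged{best_deme, next_node, t, A.c0 + B.c0, A.c1 + B.c1};
      ++next_node;
      int hi = ia > ib ? ia : ib, lo = ia > ib ? ib : ia;
      lin.erase(lin.begin() + hi);
      lin.erase(lin.begin() + lo);
      lin.push_back(merged);
    } else {
      double u = rng.u01() * Mtot;
      int idx = -1;
      double acc = 0.0;
      for (size_t i = 0; i < lin.size(); ++i) {
        acc += outm[lin[i].deme];
        if (u < acc) { idx = (int)i; break; }
      }
      if (idx < 0) idx = (int)lin.size() - 1;
      int src = lin[idx].deme;
      double u2 = rng.u01() * outm[src];
      int dst = -1;
      acc = 0.0;
      for (int j = 0; j < nd; ++j) {
        acc += mig[src * nd + j];
        if (u2 < acc) { dst = j; break; }
      }
      if (dst < 0) dst = nd - 1;
      lin[idx].deme = dst;
    }
  }
}

// [[Rcpp::export]]
List sim_genealogy_cpp(List dem, IntegerVector samp, int seed, int rep) {
  DemModel M = parse_dem(dem);
  int n = 0;
  for (int d = 0; d < M.n_demes; ++d) n += samp[d];
  std::vector<int> grp(M.n_demes, 0);
  std::vector<int> parent, leaf_deme(n, 0);
  std::vector<double> ntime;
  Rng rng(rep_state(seed, rep));
  simulate_one(M, samp, grp, rng, true, &parent, &ntime, &leaf_deme, nullptr, 0,
               false);
  int n_nodes = 2 * n - 1;
  IntegerMatrix edge(n_nodes - 1, 2);
  int e = 0;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] < 0) continue;
    edge(e, 0) = parent[i] + 1;
    edge(e, 1) = i + 1;
    ++e;
  }
  NumericVector nt(n_nodes);
  for (int i = 0; i < n_nodes; ++i) nt[i] = ntime[i];
  IntegerVector ld(n);
  for (int i = 0; i < n; ++i) ld[i] = leaf_deme[i] + 1;
  return List::create(_["edge"] = edge, _["node_time"] = nt,
                      _["leaf_deme"] = ld);
}

// Mean per-entry subtended branch length over n_sims replicate genealogies.
// grp maps each deme (0-based) to SFS dimension 0 or 1; result is a
// (n1+1) x (n2+1) matrix (n2 = 0 collapses to a single column) indexed by
// unfolded derived-leaf counts.
// [[Rcpp::export]]
NumericMatrix branch_sfs_batch_cpp(List dem, IntegerVector samp,
                                   IntegerVector grp, int n_sims, int seed,
                                   bool rao_blackwell) {
  DemModel M = parse_dem(dem);
  std::vector<int> g(M.n_demes);
  int n1 = 0, n2 = 0;
  bool two_d = false;
  for (int d = 0; d < M.n_demes; ++d) {
    g[d] = grp[d];
    if (g[d] == 0) n1 += samp[d];
    else { n2 += samp[d]; two_d = true; }
  }
  int dim1 = n1 + 1, dim2 = two_d ? n2 + 1 : 1;
  std::vector<double> acc((size_t)dim1 * dim2, 0.0);
  // exchangeable (single-deme) runs: exact per-level class composition
  std::vector<double> levelP;
  bool use_levelP = rao_blackwell && M.n_demes == 1 && !two_d && n1 >= 2;
  if (use_levelP) {
    int n = n1;
    levelP.assign((size_t)(n + 1) * (n + 1), 0.0);
    for (int k = 2; k <= n; ++k)
      for (int i = 1; i <= n - k + 1; ++i)
        levelP[(size_t)k * (n + 1) + i] =
          std::exp(R::lchoose(n - i - 1, k - 2) - R::lchoose(n - 1, k - 1));
  }
  for (int rep = 0; rep < n_sims; ++rep) {
    Rng rng(rep_state(seed, rep));
    simulate_one(M, samp, g, rng, false, nullptr, nullptr, nullptr,
                 acc.data(), dim1, rao_blackwell,
                 use_levelP ? &levelP : nullptr, n1);
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(dim1, dim2);
  for (size_t i = 0; i < acc.size(); ++i) out[i] = acc[i] / n_sims;
  return out;
}
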