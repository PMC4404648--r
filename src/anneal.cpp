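#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Exact comparison of two hierarchy scores num/den (counts are small
// integers, so 64-bit cross-multiplication never overflows).
// Returns +1 if a > b, 0 if equal, -1 if a < b. A zero denominator with
// positive numerator is +infinity; num = den = 0 cannot occur for a
// network with edges.
static inline int cmp_score(int64_t num_a, int64_t den_a,
                            int64_t num_b, int64_t den_b) {
  int64_t lhs = num_a * den_b;
  int64_t rhs = num_b * den_a;
  if (lhs > rhs) return 1;
  if (lhs < rhs) return -1;
  return 0;
}

struct Incidence {
  // CSR lists of non-self-loop edges incident to each node
  std::vector<int> offset;     // n + 1
  std::vector<int> nbr;        // other endpoint
  std::vector<char> is_out;    // 1 if the edge leaves the node
};

static Incidence build_incidence(int n, const IntegerVector &src,
                                 const IntegerVector &dst) {
  int m = src.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    if (src[e] == dst[e]) continue; // self-loops are level-invariant
    ++deg[src[e]];
    ++deg[dst[e]];
  }
  Incidence inc;
  inc.offset.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) inc.offset[v + 1] = inc.offset[v] + deg[v];
  inc.nbr.assign(inc.offset[n], 0);
  inc.is_out.assign(inc.offset[n], 0);
  std::vector<int> pos(inc.offset.begin(), inc.offset.end() - 1);
  for (int e = 0; e < m; ++e) {
    int u = src[e], v = dst[e];
    if (u == v) continue;
    inc.nbr[pos[u]] = v; inc.is_out[pos[u]] = 1; ++pos[u];
    inc.nbr[pos[v]] = u; inc.is_out[pos[v]] = 0; ++pos[v];
  }
  return inc;
}

// Simulated-annealing maximisation of the hierarchy score
// HS = (Nd + Nh) / (Nu + Nh) over level assignments in 1..L.
// Energy is -HS; a move is accepted when it lowers the energy, otherwise
// with probability exp(-dE / (C T)) under a geometric cooling schedule
// T_t = T0 * alpha^t. Infinite-HS states (Nu = Nh = 0) are compared via
// exact integer arithmetic, so a perfect state is never abandoned by the
// stochastic rule (dE = +inf). The best assignment ever visited is
// returned, not the final state.
//
// src/dst are 0-based endpoint indices; init is either empty (uniform
// random initial assignment per run) or a full 1..L assignment reused by
// every run. One RNG per run, seeded from seeds[r], makes runs
// independent and reproducible.
// [[Rcpp::export]]
List anneal_runs_cpp(int n_nodes, IntegerVector src, IntegerVector dst,
                     int L, int steps, int runs, double t0, double alpha,
                     double cconst, NumericVector seeds,
                     IntegerVector init) {
  const int n = n_nodes;
  const int m = src.size();
  if ((int)seeds.size() != runs) stop("need one seed per run");
  Incidence inc = build_incidence(n, src, dst);

  int n_self = 0;
  for (int e = 0; e < m; ++e) if (src[e] == dst[e]) ++n_self;

  IntegerMatrix best_asg(runs, n);
  NumericVector best_num(runs), best_den(runs);

  for (int r = 0; r < runs; ++r) {
    std::mt19937_64 rng((uint64_t)seeds[r]);
    std::uniform_int_distribution<int> pick_node(0, n - 1);
    std::uniform_int_distribution<int> pick_level(1, L);
    std::uniform_int_distribution<int> pick_other(1, L - 1);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<int> lvl(n);
    if (init.size() == n) {
      for (int v = 0; v < n; ++v) lvl[v] = init[v];
    } else {
      for (int v = 0; v < n; ++v) lvl[v] = pick_level(rng);
    }

    // initial class counts
    int64_t nd = 0, nu = 0, nh = n_self;
    for (int e = 0; e < m; ++e) {
      if (src[e] == dst[e]) continue;
      int a = lvl[src[e]], b = lvl[dst[e]];
      if (a > b) ++nd; else if (a < b) ++nu; else ++nh;
    }

    std::vector<int> best = lvl;
    int64_t bnum = nd + nh, bden = nu + nh;

    double T = t0;
    for (int t = 0; t < steps; ++t, T *= alpha) {
      int v = pick_node(rng);
      int old_lvl = lvl[v];
      int new_lvl = pick_other(rng);     // uniform over the other L-1 levels
      if (new_lvl >= old_lvl) ++new_lvl;

      int64_t nd2 = nd, nu2 = nu, nh2 = nh;
      for (int p = inc.offset[v]; p < inc.offset[v + 1]; ++p) {
        int w = inc.nbr[p];
        int lw = lvl[w];
        int a_old, b_old, a_new, b_new;
        if (inc.is_out[p]) { a_old = old_lvl; b_old = lw; a_new = new_lvl; b_new = lw; }
        else               { a_old = lw; b_old = old_lvl; a_new = lw; b_new = new_lvl; }
        if (a_old > b_old) --nd2; else if (a_old < b_old) --nu2; else --nh2;
        if (a_new > b_new) ++nd2; else if (a_new < b_new) ++nu2; else ++nh2;
      }

      int64_t num_old = nd + nh, den_old = nu + nh;
      int64_t num_new = nd2 + nh2, den_new = nu2 + nh2;
      int c = cmp_score(num_new, den_new, num_old, den_old);
      bool accept;
      if (c >= 0) {
        accept = true;                      // dE <= 0
      } else if (den_old == 0) {
        accept = false;                     // leaving a +inf state: dE = +inf
      } else {
        double hs_old = (double)num_old / (double)den_old;
        double hs_new = (den_new > 0) ? (double)num_new / (double)den_new
                                      : R_PosInf; // cannot happen when c < 0
        double dE = hs_old - hs_new;        // > 0 here
        accept = unif(rng) < std::exp(-dE / (cconst * T));
      }
      if (accept) {
        lvl[v] = new_lvl;
        nd = nd2; nu = nu2; nh = nh2;
        if (cmp_score(nd + nh, nu + nh, bnum, bden) > 0) {
          bnum = nd + nh; bden = nu + nh;
          best = lvl;
        }
      }
    }

    for (int v = 0; v < n; ++v) best_asg(r, v) = best[v];
    best_num[r] = (double)bnum;
    best_den[r] = (double)bden;
    if (r % 16 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["assignments"] = best_asg,
                      _["num"] = best_num,
                      _["den"] = best_den);
}
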