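#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Synchronous public-goods-game dynamics with Fermi-rule imitation.
//
// Hyperedges arrive as a CSR layout (e_ptr / e_mem, 0-based) and the
// 2-section adjacency as a second CSR (a_ptr / a_idx). Per round, every
// player's payoff is recomputed from scratch (payoffs are per-round, not
// accumulated):
//   f(i) = b * sum_{e : i in e} (alpha / m_e) * nc_e  -  b * K(i) * sigma_i
// which is the per-group PGG payoff summed over incident hyperedges
// (nc_e counts cooperators in e including i; K(i) is the generalized degree).
// Then every player draws one 2-section neighbour uniformly at random and
// adopts its strategy with Fermi probability 1/(1+exp(-beta*(f_j - f_i))).
// All updates are applied simultaneously. If the drawn neighbour has the same
// strategy the update is a no-op and no Fermi variate is consumed (keeps the
// RNG stream accounting deterministic). Isolated vertices are frozen.
//
// Uses R's RNG (unif_rand) so set.seed() on the R side makes runs exactly
// reproducible.
// [[Rcpp::export]]
List cpp_run_pgg(int n, IntegerVector e_ptr, IntegerVector e_mem,
                 IntegerVector a_ptr, IntegerVector a_idx,
                 IntegerVector sigma0, double alpha, double b, double beta,
                 int tmax, bool record_traj) {
  const int n_edges = e_ptr.size() - 1;
  std::vector<int> sigma(sigma0.begin(), sigma0.end());
  std::vector<int> signew(n);
  std::vector<double> f(n);
  std::vector<int> K(n, 0);
  std::vector<double> coef(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    int m = e_ptr[e + 1] - e_ptr[e];
    coef[e] = alpha / m;
    for (int q = e_ptr[e]; q < e_ptr[e + 1]; ++q) K[e_mem[q]]++;
  }

  int c = 0;
  for (int i = 0; i < n; ++i) c += sigma[i];

  std::vector<double> traj;
  if (record_traj) traj.push_back((double)c / n);

  int t_conv = 0;
  bool absorbed = (c == 0 || c == n);

  RNGScope scope;
  int t = 0;
  while (!absorbed && t < tmax) {
    ++t;
    // payoffs
    std::fill(f.begin(), f.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      int nc = 0;
      for (int q = e_ptr[e]; q < e_ptr[e + 1]; ++q) nc += sigma[e_mem[q]];
      if (nc == 0) continue;
      double add = b * coef[e] * nc;
      for (int q = e_ptr[e]; q < e_ptr[e + 1]; ++q) f[e_mem[q]] += add;
    }
    for (int i = 0; i < n; ++i) if (sigma[i]) f[i] -= b * K[i];

    // synchronous imitation
    for (int i = 0; i < n; ++i) {
      int deg = a_ptr[i + 1] - a_ptr[i];
      if (deg == 0) { signew[i] = sigma[i]; continue; }
      int pick = (int)(unif_rand() * deg);
      if (pick == deg) pick = deg - 1;  // guard the unit boundary
      int j = a_idx[a_ptr[i] + pick];
      if (sigma[j] == sigma[i]) { signew[i] = sigma[i]; continue; }
      double pr = 1.0 / (1.0 + std::exp(-beta * (f[j] - f[i])));
      signew[i] = (unif_rand() < pr) ? sigma[j] : sigma[i];
    }
    std::swap(sigma, signew);

    c = 0;
    for (int i = 0; i < n; ++i) c += sigma[i];
    if (record_traj) traj.push_back((double)c / n);
    if (c == 0 || c == n) { absorbed = true; t_conv = t; }
  }
  if (!absorbed) t_conv = tmax;

  return List::create(
    _["sigma"] = IntegerVector(sigma.begin(), sigma.end()),
    _["c_final"] = (double)c / n,
    _["t_conv"] = t_conv,
    _["absorbed"] = absorbed,
    _["c_traj"] = record_traj ? NumericVector(traj.begin(), traj.end())
                              : NumericVector(0));
}

typedef std::vector<std::set<int> > AdjSet;

static inline int tri_count(const AdjSet &adj, int v) {
  // number of edges among the neighbours of v (= triangles through v)
  int cnt = 0;
  const std::set<int> &nv = adj[v];
  for (std::set<int>::const_iterator it = nv.begin(); it != nv.end(); ++it) {
    const std::set<int> &nu = adj[*it];
    for (std::set<int>::const_iterator jt = nv.begin(); jt != nv.end(); ++jt) {
      if (*jt > *it && nu.count(*jt)) ++cnt;
    }
  }
  return cnt;
}

static void common_neighbours(const AdjSet &adj, int x, int y,
                              std::set<int> &out) {
  const std::set<int> &a = adj[x];
  const std::set<int> &b = adj[y];
  for (std::set<int>::const_iterator it = a.begin(); it != a.end(); ++it) {
    if (b.count(*it)) out.insert(*it);
  }
}

static AdjSet build_adj(int n, const IntegerMatrix &el) {
  AdjSet adj(n);
  for (int r = 0; r < el.nrow(); ++r) {
    adj[el(r, 0)].insert(el(r, 1));
    adj[el(r, 1)].insert(el(r, 0));
  }
  return adj;
}

static IntegerMatrix adj_to_el(const AdjSet &adj) {
  int n = adj.size();
  std::vector<int> ea, eb;
  for (int v = 0; v < n; ++v) {
    for (std::set<int>::const_iterator it = adj[v].begin();
         it != adj[v].end(); ++it) {
      if (*it > v) { ea.push_back(v); eb.push_back(*it); }
    }
  }
  IntegerMatrix out(ea.size(), 2);
  for (size_t r = 0; r < ea.size(); ++r) { out(r, 0) = ea[r]; out(r, 1) = eb[r]; }
  return out;
}

static inline int pick_nb(const std::set<int> &s) {
  int k = (int)(unif_rand() * s.size());
  if (k == (int)s.size()) k = s.size() - 1;
  std::set<int>::const_iterator it = s.begin();
  std::advance(it, k);
  return *it;
}

// Degree- and local-clustering-preserving randomization. Each step draws two
// vertices u, v, one incident link each (u-a, v-b) and proposes the exchange
// u-b / v-a. The step is accepted only if the triangle count (hence local
// clustering, degrees being fixed) of every vertex it could affect is
// unchanged: the four endpoints plus all common neighbours of the removed and
// added vertex pairs. Rejected proposals are retried; `n_steps` counts
// accepted swaps, with a hard attempt cap.
// [[Rcpp::export]]
List cpp_rewire_clustering(int n, IntegerMatrix el, int n_steps,
                           double max_attempts) {
  AdjSet adj = build_adj(n, el);
  RNGScope scope;
  int accepted = 0;
  double attempts = 0;
  while (accepted < n_steps && attempts < max_attempts) {
    ++attempts;
    int u = (int)(unif_rand() * n); if (u == n) u = n - 1;
    int v = (int)(unif_rand() * n); if (v == n) v = n - 1;
    if (u == v || adj[u].empty() || adj[v].empty()) continue;
    int a = pick_nb(adj[u]);
    int b = pick_nb(adj[v]);
    if (a == b || b == u || a == v) continue;
    if (adj[u].count(b) || adj[v].count(a)) continue;

    std::set<int> affected;
    affected.insert(u); affected.insert(v); affected.insert(a); affected.insert(b);
    common_neighbours(adj, u, a, affected);
    common_neighbours(adj, v, b, affected);
    common_neighbours(adj, u, b, affected);
    common_neighbours(adj, v, a, affected);

    std::vector<int> before;
    for (std::set<int>::iterator it = affected.begin(); it != affected.end(); ++it)
      before.push_back(tri_count(adj, *it));

    adj[u].erase(a); adj[a].erase(u);
    adj[v].erase(b); adj[b].erase(v);
    adj[u].insert(b); adj[b].insert(u);
    adj[v].insert(a); adj[a].insert(v);

    bool ok = true;
    int idx = 0;
    for (std::set<int>::iterator it = affected.begin(); it != affected.end(); ++it) {
      if (tri_count(adj, *it) != before[idx++]) { ok = false; break; }
    }
    if (ok) {
      ++accepted;
    } else {
      adj[u].erase(b); adj[b].erase(u);
      adj[v].erase(a); adj[a].erase(v);
      adj[u].insert(a); adj[a].insert(u);
      adj[v].insert(b); adj[b].insert(v);
    }
  }
  return List::create(_["edgelist"] = adj_to_el(adj),
                      _["accepted"] = accepted,
                      _["attempts"] = attempts);
}

// Randomization preserving degree correlations up to second order (the joint
// 3K-distribution over 2-paths). Two vertices are drawn and kept only if
// their degrees match; one incident link each is drawn and the exchange is
// performed only if the degrees of the two far endpoints also match.
// [[Rcpp::export]]
List cpp_rewire_3k(int n, IntegerMatrix el, int n_steps, double max_attempts) {
  AdjSet adj = build_adj(n, el);
  RNGScope scope;
  int accepted = 0;
  double attempts = 0;
  while (accepted < n_steps && attempts < max_attempts) {
    ++attempts;
    int u = (int)(unif_rand() * n); if (u == n) u = n - 1;
    int v = (int)(unif_rand() * n); if (v == n) v = n - 1;
    if (u == v || adj[u].empty() || adj[v].empty()) continue;
    if (adj[u].size() != adj[v].size()) continue;
    int a = pick_nb(adj[u]);
    int b = pick_nb(adj[v]);
    if (a == b || b == u || a == v) continue;
    if (adj[a].size() != adj[b].size()) continue;
    if (adj[u].count(b) || adj[v].count(a)) continue;
    adj[u].erase(a); adj[a].erase(u);
    adj[v].erase(b); adj[b].erase(v);
    adj[u].insert(b); adj[b].insert(u);
    adj[v].insert(a); adj[a].insert(v);
    ++accepted;
  }
  return List::create(_["edgelist"] = adj_to_el(adj),
                      _["accepted"] = accepted,
                      _["attempts"] = attempts);
}
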