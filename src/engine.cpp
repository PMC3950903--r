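// Monte-Carlo replicate engine for the TMRCA estimator: backward
// allocation of coalescent waiting times onto each rooted gene tree and
// multinomial allocation of mutations across the spanned coalescent
// intervals.  Mirrors the R reference implementation in R/tmrca.R; the two
// code paths are cross-checked in the test suite.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeSpec {
  std::vector<int> parent;                 // 0-based, -1 for root
  std::vector<std::vector<int>> children;
  std::vector<int> mult;                   // >0 for leaf groups
  std::vector<int> nsites;                 // mutations on edge above node
  std::vector<int> cnt0;                   // initial active leaves in subtree
};

TreeSpec make_spec(const List& spec) {
  TreeSpec t;
  IntegerVector parent = spec["parent"];
  IntegerVector mult = spec["mult"];
  IntegerVector nsites = spec["nsites"];
  int k = parent.size();
  t.parent.assign(parent.begin(), parent.end());
  t.mult.assign(mult.begin(), mult.end());
  t.nsites.assign(nsites.begin(), nsites.end());
  t.children.resize(k);
  for (int i = 0; i < k; ++i)
    if (t.parent[i] >= 0) t.children[t.parent[i]].push_back(i);
  t.cnt0.assign(k, 0);
  for (int i = k - 1; i >= 0; --i) {       // preorder: children after parent
    if (t.mult[i] > 0) t.cnt0[i] = t.mult[i];
    else {
      int s = 0;
      for (int c : t.children[i]) s += t.cnt0[c];
      t.cnt0[i] = s;
    }
  }
  return t;
}

// one replicate on one tree: allocate waiting times, then mutations;
// returns sum_i (k_i + 1) * coef_i given precomputed sum(coef) = base
double replicate_tree(const TreeSpec& t, const std::vector<double>& w,
                      const std::vector<double>& coef, double base, int n) {
  int k = (int)t.parent.size();
  std::vector<int> cnt(t.cnt0);
  std::vector<int> merge_step(k, 0), comp_step(k, 0);
  std::vector<std::vector<int>> slots(k);  // child id, or -1 = intermediate
  for (int v = 0; v < k; ++v) {
    if (t.mult[v] == 0)
      for (int c : t.children[v])
        if (cnt[c] == 1) slots[v].push_back(c);
    if (cnt[v] == 1) comp_step[v] = n + 1; // coalesced from the start
  }
  for (int i = n; i >= 2; --i) {
    int v = 0;
    for (;;) {
      double total = 0.0;
      for (int c : t.children[v]) if (cnt[c] >= 2) total += cnt[c];
      int navail = (int)slots[v].size();
      if (navail >= 2) total += navail;
      if (total <= 0.0) stop("internal error: no mergeable unit");
      double r = unif_rand() * total;
      int pick = -2;                       // -1 => merge here
      for (int c : t.children[v]) {
        if (cnt[c] < 2) continue;
        r -= cnt[c];
        if (r < 0.0) { pick = c; break; }
      }
      if (pick == -2) pick = -1;
      if (pick == -1) {                    // merge among available ancestors
        int a = (int)(unif_rand() * navail); if (a >= navail) a = navail - 1;
        int b = (int)(unif_rand() * (navail - 1));
        if (b >= navail - 1) b = navail - 2;
        if (b >= a) ++b;
        int ua = slots[v][a], ub = slots[v][b];
        if (ua >= 0) merge_step[ua] = i;
        if (ub >= 0) merge_step[ub] = i;
        int hi = a > b ? a : b, lo = a > b ? b : a;
        slots[v].erase(slots[v].begin() + hi);
        slots[v].erase(slots[v].begin() + lo);
        slots[v].push_back(-1);
        for (int p = v; p >= 0; p = t.parent[p]) --cnt[p];
        if (cnt[v] == 1) {
          comp_step[v] = i;
          if (v > 0) slots[t.parent[v]].push_back(v);
        }
        break;
      } else if (t.mult[pick] > 0) {       // merge within identical leaves
        for (int p = pick; p >= 0; p = t.parent[p]) --cnt[p];
        if (cnt[pick] == 1) {
          comp_step[pick] = i;
          slots[v].push_back(pick);
        }
        break;
      } else v = pick;                     // descend into the subtree
    }
  }
  // mutations: segment above node v spans intervals merge_step[v] ..
  // comp_step[v]-1; each mutation falls in interval j with probability
  // proportional to w[j]
  double acc = base;
  for (int v = 1; v < k; ++v) {
    int tr = t.nsites[v];
    if (tr == 0) continue;
    int lo = merge_step[v], hi = comp_step[v] - 1;
    if (lo < 2 || hi < lo) stop("internal error: empty segment span");
    double len = 0.0;
    for (int j = lo; j <= hi; ++j) len += w[j];
    for (int m = 0; m < tr; ++m) {
      double r = unif_rand() * len;
      int j = lo;
      for (; j < hi; ++j) { r -= w[j]; if (r < 0.0) break; }
      acc += coef[j];
    }
  }
  return acc;
}

}  // namespace

// For M replicates, draw one waiting-time vector shared across all trees
// and return the matrix of per-tree values sum_i (k_{r,i} + 1) * coef_i
// (rows = replicates, cols = trees).
// [[Rcpp::export]]
NumericMatrix cpp_estimate_batch(List treespecs, int n, double theta,
                                 int M) {
  int R = treespecs.size();
  std::vector<TreeSpec> trees;
  trees.reserve(R);
  for (int r = 0; r < R; ++r) trees.push_back(make_spec(treespecs[r]));
  std::vector<double> w(n + 1, 0.0), coef(n + 1, 0.0);
  double base = 0.0;
  for (int i = 2; i <= n; ++i) {
    coef[i] = 1.0 / (i * (i + theta - 1.0));
    base += coef[i];
  }
  NumericMatrix out(M, R);
  for (int m = 0; m < M; ++m) {
    for (int i = 2; i <= n; ++i)
      w[i] = -2.0 / (i * (i - 1.0)) * std::log1p(-unif_rand());
    for (int r = 0; r < R; ++r)
      out(m, r) = replicate_tree(trees[r], w, coef, base, n);
  }
  return out;
}
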