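#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Joint inclusive dominance count: out[i] = #{j : p1[j] <= p1[i] && p2[j] <= p2[i]}.
// Fenwick tree over p1 ranks, sweeping p2 in ascending order; tie groups in p2
// are inserted before being queried so both comparisons stay inclusive.
// [[Rcpp::export]]
IntegerVector count_joint_leq(NumericVector p1, NumericVector p2) {
  const int n = p1.size();
  if (p2.size() != n) stop("p1 and p2 must have equal length");
  std::vector<double> uv(p1.begin(), p1.end());
  std::sort(uv.begin(), uv.end());
  uv.erase(std::unique(uv.begin(), uv.end()), uv.end());
  const int m = uv.size();
  std::vector<int> r1(n);
  for (int i = 0; i < n; ++i)
    r1[i] = int(std::lower_bound(uv.begin(), uv.end(), p1[i]) - uv.begin()) + 1;
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return p2[a] < p2[b]; });
  std::vector<int> bit(m + 1, 0);
  IntegerVector out(n);
  int k = 0;
  while (k < n) {
    int k2 = k;
    while (k2 < n && p2[ord[k2]] == p2[ord[k]]) ++k2;
    for (int t = k; t < k2; ++t)
      for (int i = r1[ord[t]]; i <= m; i += i & -i) ++bit[i];
    for (int t = k; t < k2; ++t) {
      int s = 0;
      for (int i = r1[ord[t]]; i > 0; i -= i & -i) s += bit[i];
      out[ord[t]] = s;
    }
    k = k2;
  }
  return out;
}

// Greedy LD pruning: visit SNPs in `order` (1-based), keep a SNP iff no
// already-kept SNP is adjacent (r2 above threshold) to it. Adjacency is CSR
// with 0-based indices in adj_idx and 0-based offsets in adj_ptr.
// [[Rcpp::export]]
LogicalVector greedy_prune(IntegerVector order, IntegerVector adj_ptr,
                           IntegerVector adj_idx) {
  const int n = order.size();
  LogicalVector keep(n, false);
  std::vector<char> kept(n, 0);
  for (int t = 0; t < n; ++t) {
    int s = order[t] - 1;
    bool ok = true;
    for (int j = adj_ptr[s]; j < adj_ptr[s + 1]; ++j)
      if (kept[adj_idx[j]]) { ok = false; break; }
    if (ok) { kept[s] = 1; keep[s] = true; }
  }
  return keep;
}
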