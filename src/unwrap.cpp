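#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Two-dimensional phase unwrapping by sorting reliability following a
// non-continuous path (second-difference reliability, edge-wise region
// merging).  Pixels are joined in order of decreasing edge reliability;
// each join adds the integer multiple of 2*pi that makes the two touching
// pixels differ by less than pi.  Runs in O(N log N).

static inline double wrap2pi(double d) {
  return d - 2.0 * M_PI * std::floor(d / (2.0 * M_PI) + 0.5);
}

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
NumericMatrix unwrap2d_cpp(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  const double* phi = wrapped.begin();

  // per-pixel second-difference measure D (small D = reliable)
  std::vector<double> D(n, 1e10);  // border pixels: low reliability
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const int p = i + j * nr;
      double H  = wrap2pi(phi[p - 1]      - phi[p]) - wrap2pi(phi[p] - phi[p + 1]);
      double V  = wrap2pi(phi[p - nr]     - phi[p]) - wrap2pi(phi[p] - phi[p + nr]);
      double D1 = wrap2pi(phi[p - nr - 1] - phi[p]) - wrap2pi(phi[p] - phi[p + nr + 1]);
      double D2 = wrap2pi(phi[p + nr - 1] - phi[p]) - wrap2pi(phi[p] - phi[p - nr + 1]);
      D[p] = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
    }
  }

  // edges: vertical (p, p+1) within a column, horizontal (p, p+nr)
  const int n_ev = (nr - 1) * nc, n_eh = nr * (nc - 1);
  const int n_e = n_ev + n_eh;
  std::vector<int> ea(n_e), eb(n_e);
  std::vector<double> erel(n_e);
  int e = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i, ++e) {
      int p = i + j * nr;
      ea[e] = p; eb[e] = p + 1; erel[e] = D[p] + D[p + 1];
    }
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i, ++e) {
      int p = i + j * nr;
      ea[e] = p; eb[e] = p + nr; erel[e] = D[p] + D[p + nr];
    }
  std::vector<int> order(n_e);
  for (int k = 0; k < n_e; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return erel[a] < erel[b]; });

  // union-find with per-group member lists so wrap counts can be updated
  std::vector<int> parent(n), head(n), tail(n), nxt(n, -1), gsize(n, 1);
  std::vector<int> wraps(n, 0);
  for (int p = 0; p < n; ++p) { parent[p] = p; head[p] = p; tail[p] = p; }
  auto find = [&](int p) {
    while (parent[p] != p) { parent[p] = parent[parent[p]]; p = parent[p]; }
    return p;
  };

  for (int k = 0; k < n_e; ++k) {
    const int a = ea[order[k]], b = eb[order[k]];
    int ra = find(a), rb = find(b);
    if (ra == rb) continue;
    // adjust the smaller group; delta applied to b's group if kept as is
    double va = phi[a] + 2.0 * M_PI * wraps[a];
    double vb = phi[b] + 2.0 * M_PI * wraps[b];
    int delta = (int)std::lround((va - vb) / (2.0 * M_PI));
    int keep = ra, move = rb, dmove = delta;
    if (gsize[rb] > gsize[ra]) { keep = rb; move = ra; dmove = -delta; }
    if (dmove != 0)
      for (int p = head[move]; p != -1; p = nxt[p]) wraps[p] += dmove;
    nxt[tail[keep]] = head[move];
    tail[keep] = tail[move];
    gsize[keep] += gsize[move];
    parent[move] = keep;
  }

  NumericMatrix out(nr, nc);
  for (int p = 0; p < n; ++p) out[p] = phi[p] + 2.0 * M_PI * wraps[p];
  return out;
}
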