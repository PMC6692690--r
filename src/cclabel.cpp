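#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Label maximal 4-connected regions of constant value in an integer matrix
// (two-pass union-find).  Components are numbered 1..n_components in
// row-major order of first appearance; every pixel gets a component id.
// [[Rcpp::export]]
IntegerMatrix cc_label_values(IntegerMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve((size_t)H * W / 4);

  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const int v = x(i, j);
      int up = (i > 0 && x(i - 1, j) == v) ? lab(i - 1, j) : -1;
      int left = (j > 0 && x(i, j - 1) == v) ? lab(i, j - 1) : -1;
      if (up < 0 && left < 0) {
        const int id = (int)parent.size();
        parent.push_back(id);
        lab(i, j) = id;
      } else if (up >= 0 && left < 0) {
        lab(i, j) = up;
      } else if (up < 0) {
        lab(i, j) = left;
      } else {
        const int ru = uf_find(parent, up), rl = uf_find(parent, left);
        lab(i, j) = rl;
        if (ru != rl) parent[std::max(ru, rl)] = std::min(ru, rl);
      }
    }
  }
  // second pass: resolve roots, renumber in order of first appearance
  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      const int r = uf_find(parent, lab(i, j));
      if (newid[r] == 0) newid[r] = ++next;
      lab(i, j) = newid[r];
    }
  return lab;
}
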