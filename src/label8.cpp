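#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a logical/numeric matrix.
// Two-pass union-find; labels are 1..n in raster order of first pixel.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label8(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j)) continue;
      // neighbours already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int nb[4] = {0, 0, 0, 0};
      if (i > 0)            nb[0] = lab(i - 1, j);
      if (i > 0 && j > 0)   nb[1] = lab(i - 1, j - 1);
      if (j > 0)            nb[2] = lab(i, j - 1);
      if (i < nr - 1 && j > 0) nb[3] = lab(i + 1, j - 1);
      int m = 0;
      for (int k = 0; k < 4; ++k) if (nb[k] > 0 && (m == 0 || nb[k] < m)) m = nb[k];
      if (m == 0) {
        int newlab = (int)parent.size();
        parent.push_back(newlab);
        lab(i, j) = newlab;
      } else {
        lab(i, j) = m;
        int rm = find_root(parent, m);
        for (int k = 0; k < 4; ++k) {
          if (nb[k] > 0) {
            int r = find_root(parent, nb[k]);
            if (r != rm) parent[r] = rm;
          }
        }
      }
    }
  }

  // second pass: flatten and renumber consecutively in raster order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++next;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
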