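#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image neighbor pairs inside an orthorhombic box via a cell list.
//
// pos:     n x 3 coordinates (may be unwrapped; wrapped internally)
// type:    1-based element-type index per atom
// cutoff2: squared cutoff per unordered type pair (0 => pair never bonds)
// box:     three edge lengths
//
// Falls back to an O(n^2) scan when the box supports fewer than 3 cells in
// any direction (the cell walk would double-count images there).
// [[Rcpp::export]]
DataFrame neighbor_pairs_cpp(NumericMatrix pos, IntegerVector type,
                             NumericMatrix cutoff2, NumericVector box) {
  const int n = pos.nrow();
  double maxcut2 = 0.0;
  for (int a = 0; a < cutoff2.nrow(); ++a)
    for (int b = 0; b < cutoff2.ncol(); ++b)
      if (cutoff2(a, b) > maxcut2) maxcut2 = cutoff2(a, b);
  const double maxcut = std::sqrt(maxcut2);

  std::vector<int> out_i, out_j;
  std::vector<double> out_d;

  // wrapped copies for cell assignment
  std::vector<double> w(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double x = pos(i, k) - box[k] * std::floor(pos(i, k) / box[k]);
      if (x < 0 || x >= box[k]) x = 0;  // guard FP edge
      w[3 * i + k] = x;
    }

  auto consider = [&](int i, int j) {
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = pos(i, k) - pos(j, k);
      d -= box[k] * std::nearbyint(d / box[k]);
      d2 += d * d;
    }
    double c2 = cutoff2(type[i] - 1, type[j] - 1);
    if (c2 > 0.0 && d2 <= c2) {
      out_i.push_back(i + 1);
      out_j.push_back(j + 1);
      out_d.push_back(std::sqrt(d2));
    }
  };

  int nc[3];
  bool cells_ok = true;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / maxcut);
    if (nc[k] < 3) cells_ok = false;
    if (nc[k] > 400) nc[k] = 400;
  }

  if (!cells_ok || n < 64) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  } else {
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1);
    auto cell_of = [&](int i) {
      int c[3];
      for (int k = 0; k < 3; ++k) {
        c[k] = (int)(w[3 * i + k] / box[k] * nc[k]);
        if (c[k] >= nc[k]) c[k] = nc[k] - 1;
      }
      return (c[0] * nc[1] + c[1]) * nc[2] + c[2];
    };
    for (int i = 0; i < n; ++i) {
      int c = cell_of(i);
      nxt[i] = head[c];
      head[c] = i;
    }
    for (int cx = 0; cx < nc[0]; ++cx)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cz = 0; cz < nc[2]; ++cz) {
          int c = (cx * nc[1] + cy) * nc[2] + cz;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int ex = (cx + dx + nc[0]) % nc[0];
                int ey = (cy + dy + nc[1]) % nc[1];
                int ez = (cz + dz + nc[2]) % nc[2];
                int e = (ex * nc[1] + ey) * nc[2] + ez;
                if (e < c) continue;  // visit each cell pair once
                for (int i = head[c]; i >= 0; i = nxt[i]) {
                  int jstart = (e == c) ? nxt[i] : head[e];
                  for (int j = jstart; j >= 0; j = nxt[j]) consider(i, j);
                }
              }
        }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j, _["dist"] = out_d);
}
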