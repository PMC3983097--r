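#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum distance between atoms belonging to different groups (e.g. chains),
// and the offending pair. Used for steric-clash checks at build time.
// [[Rcpp::export(name = ".min_cross_distance")]]
List min_cross_distance(NumericMatrix xyz, IntegerVector group) {
  int n = xyz.nrow();
  double best = R_PosInf;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (group[i] == group[j]) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bi = i + 1;
        bj = j + 1;
      }
    }
  }
  return List::create(_["distance"] = std::sqrt(best), _["i"] = bi, _["j"] = bj);
}

// All pairs (i, j), i from set A and j from set B, with distance <= cutoff.
// 1-based index vectors in; a two-column matrix of 1-based indices out.
// [[Rcpp::export(name = ".pairs_within")]]
IntegerMatrix pairs_within(NumericMatrix xyz, IntegerVector ia, IntegerVector ib,
                           double cutoff) {
  double c2 = cutoff * cutoff;
  std::vector<int> oi, oj;
  for (int a = 0; a < ia.size(); ++a) {
    int i = ia[a] - 1;
    for (int b = 0; b < ib.size(); ++b) {
      int j = ib[b] - 1;
      if (i == j) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        oi.push_back(ia[a]);
        oj.push_back(ib[b]);
      }
    }
  }
  IntegerMatrix out(oi.size(), 2);
  for (size_t t = 0; t < oi.size(); ++t) {
    out(t, 0) = oi[t];
    out(t, 1) = oj[t];
  }
  return out;
}
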