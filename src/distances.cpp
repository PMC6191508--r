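#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Directed surface distances: for every point (row) of A, the Euclidean
// distance to the nearest point of B.  Coordinates are in mm.  Exhaustive
// pairwise scan; surfaces of compact structures stay small enough that the
// O(|A|*|B|) cost is negligible next to the rest of the pipeline.
// [[Rcpp::export]]
NumericVector cpp_directed_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
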