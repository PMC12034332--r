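#include <Rcpp.h>
using namespace Rcpp;

// Directed nearest-neighbour distances between two point clouds.
// For each row of `a`, the Euclidean distance (mm) to the closest row of `b`.
// Arithmetic is kept identical to the plain R double loop used as the test
// oracle: squared terms accumulated x, y, z in order; sqrt applied once at
// the end of the min over squared distances.
// [[Rcpp::export]]
NumericVector nn_min_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0);
      const double dy = ay - b(j, 1);
      const double dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
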