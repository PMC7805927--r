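// Distance kernels for point-pattern statistics: plain O(n^2) loops,
// avoiding materialization of the full distance matrix.

#include <Rcpp.h>
using namespace Rcpp;

// Per-point nearest-neighbor Euclidean distance.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < out[i]) out[i] = d2;
      if (d2 < out[j]) out[j] = d2;
    }
  }
  return sqrt(out);
}

// Unordered pairs (i, j), i < j, with distance <= rmax; 1-based indices.
// [[Rcpp::export]]
List close_pairs_cpp(NumericMatrix coords, double rmax) {
  int n = coords.nrow();
  double r2 = rmax * rmax;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["d"] = wrap(dd));
}
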