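#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest-path distances by Floyd-Warshall on a dense length
// matrix. Entries <= 0 or non-finite are treated as "no edge" (length Inf);
// the diagonal is forced to 0. Dense O(N^3) is the right trade-off for
// connectome-sized graphs (N of order 100), where it beats per-call graph
// construction overhead by orders of magnitude.
// [[Rcpp::export(name = ".fw_distances")]]
NumericMatrix fw_distances(NumericMatrix lengths) {
  int n = lengths.nrow();
  if (lengths.ncol() != n) stop("length matrix must be square");
  NumericMatrix d(n, n);
  double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double v = lengths(i, j);
      d(i, j) = (i == j) ? 0.0 : ((v > 0 && R_finite(v)) ? v : inf);
    }
  }
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}
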