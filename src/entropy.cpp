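#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Template-pair match counts for sample entropy (Richman-Moorman scheme).
// Templates of length m are taken at the first N-m start points so every
// template has an (m+1)-length extension; self-matches excluded.
// Returns c(B, A): pairs within Chebyshev distance r at length m and m+1.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
      }
      if (dmax <= r) {
        B += 1.0;
        double d = std::fabs(x[i + m] - x[j + m]);
        if (d > dmax) dmax = d;
        if (dmax <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Range-distance match counts over a whole tolerance grid in one O(n^2) pass.
// d(xi, xj) = (max_k|.| - min_k|.|) / (max_k|.| + min_k|.|), in [0, 1];
// identical templates (0/0) are treated as distance 0.  For each pair the
// bin of the smallest r_grid value >= distance is incremented; cumulative
// sums then give, for every r in the grid, the count of pairs with d <= r.
// Returns a (2 x G) matrix: row 0 = B(r) (length m), row 1 = A(r) (m+1).
// [[Rcpp::export(name = ".rangeen_counts")]]
NumericMatrix rangeen_counts(NumericVector x, int m, NumericVector r_grid) {
  const int n = x.size();
  const int nt = n - m;
  const int G = r_grid.size();
  std::vector<double> grid(r_grid.begin(), r_grid.end());
  std::vector<double> binB(G + 1, 0.0), binA(G + 1, 0.0); // last bin: d > max r
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double mx = 0.0, mn = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > mx) mx = d;
        if (d < mn) mn = d;
      }
      double dm = (mx + mn > 0.0) ? (mx - mn) / (mx + mn) : 0.0;
      {
        int b = std::lower_bound(grid.begin(), grid.end(), dm) - grid.begin();
        binB[b] += 1.0;
      }
      double d = std::fabs(x[i + m] - x[j + m]);
      if (d > mx) mx = d;
      if (d < mn) mn = d;
      double dm1 = (mx + mn > 0.0) ? (mx - mn) / (mx + mn) : 0.0;
      {
        int b = std::lower_bound(grid.begin(), grid.end(), dm1) - grid.begin();
        binA[b] += 1.0;
      }
    }
  }
  NumericMatrix out(2, G);
  double cb = 0.0, ca = 0.0;
  for (int g = 0; g < G; ++g) {
    cb += binB[g];
    ca += binA[g];
    out(0, g) = cb;
    out(1, g) = ca;
  }
  return out;
}
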