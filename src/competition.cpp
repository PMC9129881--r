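#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Pairwise competition load on a wrapped strip.
//
// Each tree j deposits a triangular influence kernel of radius
// r_j = r0 + r_per_h * height_j, weighted by its basal diameter; the
// density index of tree i is the summed influence of all other trees at
// tree i's position. x wraps modulo `width` (east-west margins), y does
// not. Trees are processed through a y-sorted sliding window so the cost
// is O(n * local neighbourhood).
// [[Rcpp::export]]
NumericVector competition_index_cpp(NumericVector x, NumericVector y,
                                    NumericVector basal, NumericVector height,
                                    double width, double r0, double r_per_h) {
  const int n = x.size();
  NumericVector di(n);
  if (n < 2) return di;

  IntegerVector ord_r = seq(0, n - 1);
  std::vector<int> ord(ord_r.begin(), ord_r.end());
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = r0 + r_per_h * height[i];
    if (r > rmax) rmax = r;
  }

  int lo = 0;
  for (int ii = 0; ii < n; ++ii) {
    const int i = ord[ii];
    const double yi = y[i], xi = x[i];
    while (y[ord[lo]] < yi - rmax) ++lo;
    for (int jj = lo; jj < ii; ++jj) {
      const int j = ord[jj];
      double dy = yi - y[j];
      double dx = std::fabs(xi - x[j]);
      if (width > 0 && dx > width / 2) dx = width - dx;
      const double d = std::sqrt(dx * dx + dy * dy);
      const double ri = r0 + r_per_h * height[i];
      const double rj = r0 + r_per_h * height[j];
      if (d < rj) di[i] += basal[j] * (1.0 - d / rj);
      if (d < ri) di[j] += basal[i] * (1.0 - d / ri);
    }
  }
  return di;
}

// Deposit the same triangular kernels onto a regular grid (cell centres),
// producing the gridded competition density map. Used for the environment
// surface and for small-extent tests; the simulator itself evaluates the
// kernels exactly at tree positions.
// [[Rcpp::export]]
NumericMatrix density_field_cpp(NumericVector x, NumericVector y,
                                NumericVector basal, NumericVector height,
                                double width, double y_min, double y_max,
                                double cell, double r0, double r_per_h) {
  const int nx = std::max(1, (int)std::ceil(width / cell));
  const int ny = std::max(1, (int)std::ceil((y_max - y_min) / cell));
  NumericMatrix field(nx, ny);
  const int n = x.size();
  for (int t = 0; t < n; ++t) {
    const double r = r0 + r_per_h * height[t];
    const int cx0 = (int)std::floor((x[t] - r) / cell);
    const int cx1 = (int)std::floor((x[t] + r) / cell);
    const int cy0 = std::max(0, (int)std::floor((y[t] - r - y_min) / cell));
    const int cy1 = std::min(ny - 1, (int)std::floor((y[t] + r - y_min) / cell));
    for (int cx = cx0; cx <= cx1; ++cx) {
      int cxw = ((cx % nx) + nx) % nx;  // wrap east-west
      const double xc = (cx + 0.5) * cell;
      for (int cy = cy0; cy <= cy1; ++cy) {
        const double yc = y_min + (cy + 0.5) * cell;
        const double dx = xc - x[t], dy = yc - y[t];
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < r) field(cxw, cy) += basal[t] * (1.0 - d / r);
      }
    }
  }
  return field;
}
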