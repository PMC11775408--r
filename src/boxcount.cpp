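// Box counting over point sets: number of occupied cells of a fixed-origin
// cubic grid of side s, for each requested s. Point coordinates and box sizes
// share units.
#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_box_count_points(NumericMatrix pts, NumericVector origin,
                                   NumericVector sizes) {
  R_xlen_t n = pts.nrow();
  IntegerVector out(sizes.size());
  std::unordered_set<long long> cells;
  for (int k = 0; k < sizes.size(); ++k) {
    double s = sizes[k];
    cells.clear();
    for (R_xlen_t i = 0; i < n; ++i) {
      long long cx = (long long)std::floor((pts(i,0) - origin[0]) / s);
      long long cy = (long long)std::floor((pts(i,1) - origin[1]) / s);
      long long cz = (long long)std::floor((pts(i,2) - origin[2]) / s);
      cells.insert(((cx + 1048576LL) << 42) | ((cy + 1048576LL) << 21) | (cz + 1048576LL));
    }
    out[k] = (int)cells.size();
  }
  return out;
}

// Offset-averaged box counts: for each box size, the count of occupied cells
// averaged over a fixed set of fractional grid offsets (lattice-resonance
// suppression). offsets are fractions of the box size.
// [[Rcpp::export]]
NumericVector cpp_box_count_avg(NumericMatrix pts, NumericVector origin,
                                NumericVector sizes, NumericMatrix offsets) {
  R_xlen_t n = pts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (R_xlen_t i = 0; i < n; ++i) { px[i]=pts(i,0); py[i]=pts(i,1); pz[i]=pts(i,2); }
  NumericVector out(sizes.size());
  std::unordered_set<long long> cells;
  for (int k = 0; k < sizes.size(); ++k) {
    double s = sizes[k];
    double acc = 0;
    for (int o = 0; o < offsets.nrow(); ++o) {
      double ox = origin[0] - offsets(o,0) * s;
      double oy = origin[1] - offsets(o,1) * s;
      double oz = origin[2] - offsets(o,2) * s;
      cells.clear();
      for (R_xlen_t i = 0; i < n; ++i) {
        long long cx = (long long)std::floor((px[i] - ox) / s);
        long long cy = (long long)std::floor((py[i] - oy) / s);
        long long cz = (long long)std::floor((pz[i] - oz) / s);
        cells.insert(((cx + 1048576LL) << 42) | ((cy + 1048576LL) << 21) | (cz + 1048576LL));
      }
      acc += (double)cells.size();
    }
    out[k] = acc / offsets.nrow();
  }
  return out;
}
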