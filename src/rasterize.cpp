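// Voxelization of the synthetic lesion model: a star-convex core whose radius
// field is modulated by a multi-scale spherical bump field, plus optional
// capsule extensions (tendrils / trans-callosal bridge) and thin disc-shaped
// sheet extensions. Coordinates are mm, lesion centred at the origin.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// lookup table for exp(x) on [-12, 0], linear interpolation
namespace {
struct ExpLut {
  static const int N = 4096;
  double tab[N + 1];
  ExpLut() { for (int i = 0; i <= N; ++i) tab[i] = std::exp(-12.0 + 12.0 * i / N); }
  inline double operator()(double x) const {   // x in [-12, 0]
    double u = (x + 12.0) * (N / 12.0);
    int i = (int)u;
    if (i < 0) return 0.0;
    if (i >= N) return tab[N];
    double f = u - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};
static const ExpLut EXPL;
}

// [[Rcpp::export]]
LogicalVector cpp_rasterize_lesion(IntegerVector dim, NumericVector origin, double h,
                                   double R, double amp, double split,
                                   NumericMatrix bump_dir, NumericVector kappa,
                                   NumericVector weight,
                                   NumericMatrix capsules,  // p0(3), p1(3), radius
                                   NumericMatrix sheets) {  // normal(3), centre(3), radius, thickness
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nb = bump_dir.nrow(), ncap = capsules.nrow(), nsh = sheets.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  const double rlo = R * (1.0 + amp * (0.0 - split));   // min possible radius
  const double rhi = R * (1.0 + amp * (1.0 - split));   // max possible radius
  R_xlen_t p = 0;
  for (int kz = 0; kz < nz; ++kz) {
    double z = origin[2] + h * kz;
    for (int ky = 0; ky < ny; ++ky) {
      double y = origin[1] + h * ky;
      for (int kx = 0; kx < nx; ++kx, ++p) {
        double x = origin[0] + h * kx;
        double rr = std::sqrt(x * x + y * y + z * z);
        bool inside = false;
        if (rr <= rlo) inside = true;
        else if (rr <= rhi && nb > 0) {
          double ux = x / rr, uy = y / rr, uz = z / rr;
          double B = 0.0;
          for (int i = 0; i < nb; ++i) {
            double cosang = ux * bump_dir(i,0) + uy * bump_dir(i,1) + uz * bump_dir(i,2);
            double e = kappa[i] * (cosang - 1.0);
            if (e > -12.0) B += weight[i] * EXPL(e);
            if (B >= 1.0) break;
          }
          if (B > 1.0) B = 1.0;
          inside = rr <= R * (1.0 + amp * (B - split));
        } else if (rr <= rhi && nb == 0) {
          inside = rr <= R;
        }
        if (!inside && ncap > 0) {
          for (int i = 0; i < ncap; ++i) {
            double ax = capsules(i,3) - capsules(i,0), ay = capsules(i,4) - capsules(i,1),
                   az = capsules(i,5) - capsules(i,2);
            double len2 = ax*ax + ay*ay + az*az;
            double t = ((x - capsules(i,0))*ax + (y - capsules(i,1))*ay + (z - capsules(i,2))*az) / len2;
            if (t < 0) t = 0; if (t > 1) t = 1;
            double dx = x - (capsules(i,0) + t*ax), dy = y - (capsules(i,1) + t*ay),
                   dz = z - (capsules(i,2) + t*az);
            double cr = capsules(i,6);
            if (dx*dx + dy*dy + dz*dz <= cr*cr) { inside = true; break; }
          }
        }
        if (!inside && nsh > 0) {
          for (int i = 0; i < nsh; ++i) {
            double dxc = x - sheets(i,3), dyc = y - sheets(i,4), dzc = z - sheets(i,5);
            double dn = dxc*sheets(i,0) + dyc*sheets(i,1) + dzc*sheets(i,2);
            if (std::abs(dn) > 0.5 * sheets(i,7)) continue;
            if (dxc*dxc + dyc*dyc + dzc*dzc <= sheets(i,6)*sheets(i,6)) { inside = true; break; }
          }
        }
        out[p] = inside;
      }
    }
  }
  return out;
}
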