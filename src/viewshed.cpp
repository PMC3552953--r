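// Exact "R3" line-of-sight over a regular elevation grid.
//
// Semantics mirror the R reference implementation (line_of_sight):
// terrain is evaluated where the sightline crosses the grid lines through
// cell centres, with bilinear interpolation (which reduces to linear
// interpolation between the two adjacent cell centres on those lines);
// endpoint ground elevations are bilinear; a target in the observer's own
// cell is always visible; NA terrain anywhere under the sightline blocks.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  const NumericMatrix &z;
  int nr, nc;
  double cs, xll, yll;
  Grid(const NumericMatrix &zz, double cs_, double xll_, double yll_)
      : z(zz), nr(zz.nrow()), nc(zz.ncol()), cs(cs_), xll(xll_),
        yll(yll_) {}

  // bilinear elevation, clamped to the hull of cell centres
  double at(double x, double y) const {
    double xc1 = xll + 0.5 * cs;
    double yc1 = yll + (nr - 0.5) * cs;
    double u = (x - xc1) / cs;
    double w = (yc1 - y) / cs;
    u = std::min(std::max(u, 0.0), (double)(nc - 1));
    w = std::min(std::max(w, 0.0), (double)(nr - 1));
    int j = std::min((int)std::floor(u), std::max(nc - 2, 0));
    int i = std::min((int)std::floor(w), std::max(nr - 2, 0));
    double fx = u - j, fy = w - i;
    int j2 = std::min(j + 1, nc - 1), i2 = std::min(i + 1, nr - 1);
    double z11 = z(i, j), z12 = z(i, j2), z21 = z(i2, j), z22 = z(i2, j2);
    return (1 - fy) * ((1 - fx) * z11 + fx * z12) +
           fy * ((1 - fx) * z21 + fx * z22);
  }

  bool cell_of(double x, double y, int &row, int &col) const {
    double ytop = yll + nr * cs;
    col = (int)std::floor((x - xll) / cs);
    row = (y == ytop) ? 0 : (int)std::floor((ytop - y) / cs);
    return col >= 0 && col < nc && row >= 0 && row < nr;
  }

  bool los(double x0, double y0, double eye_h, double x1, double y1,
           double target_h) const {
    int r0, c0, r1, c1;
    if (!cell_of(x0, y0, r0, c0) || !cell_of(x1, y1, r1, c1))
      return false;
    double z0 = at(x0, y0), z1 = at(x1, y1);
    if (ISNAN(z0) || ISNAN(z1)) return false;
    if (r0 == r1 && c0 == c1) return true;
    double e0 = z0 + eye_h, e1 = z1 + target_h;
    double dx = x1 - x0, dy = y1 - y0;
    double lo, hi;
    std::vector<double> tt;
    tt.reserve(nr + nc);
    if (dx != 0) {
      lo = std::min(x0, x1);
      hi = std::max(x0, x1);
      for (int j = 0; j < nc; ++j) {
        double xc = xll + (j + 0.5) * cs;
        if (xc > lo && xc < hi) tt.push_back((xc - x0) / dx);
      }
    }
    if (dy != 0) {
      lo = std::min(y0, y1);
      hi = std::max(y0, y1);
      for (int i = 0; i < nr; ++i) {
        double yc = yll + (nr - i - 0.5) * cs;
        if (yc > lo && yc < hi) tt.push_back((yc - y0) / dy);
      }
    }
    std::sort(tt.begin(), tt.end());
    // between crossings the bilinear surface is quadratic along the ray,
    // so interval midpoints are checked as well as the crossings
    std::vector<double> pts;
    pts.reserve(2 * tt.size() + 1);
    double prev = 0.0;
    for (double t : tt) {
      pts.push_back((prev + t) / 2);
      pts.push_back(t);
      prev = t;
    }
    pts.push_back((prev + 1.0) / 2);
    for (double t : pts) {
      if (t <= 1e-12 || t >= 1 - 1e-12) continue;
      double terr = at(x0 + t * dx, y0 + t * dy);
      if (ISNAN(terr)) return false;
      if (terr > e0 + t * (e1 - e0) + 1e-9) return false;
    }
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".los_cpp")]]
bool los_cpp(NumericMatrix z, double cs, double xll, double yll, double x0,
             double y0, double eye_h, double x1, double y1,
             double target_h) {
  Grid g(z, cs, xll, yll);
  return g.los(x0, y0, eye_h, x1, y1, target_h);
}

// [[Rcpp::export(name = ".viewshed_cpp")]]
NumericMatrix viewshed_cpp(NumericMatrix z, double cs, double xll,
                           double yll, NumericVector obs_x,
                           NumericVector obs_y, NumericVector obs_h,
                           double max_distance, double target_h) {
  Grid g(z, cs, xll, yll);
  int nr = z.nrow(), nc = z.ncol(), nobs = obs_x.size();
  NumericMatrix vis(nr, nc);
  std::vector<int> ord(nobs);
  std::vector<double> d2(nobs);
  bool limited = R_finite(max_distance);
  double md2 = max_distance * max_distance;
  for (int i = 0; i < nr; ++i) {
    double ty = yll + (nr - i - 0.5) * cs;
    for (int j = 0; j < nc; ++j) {
      if (ISNAN(z(i, j))) continue;
      double tx = xll + (j + 0.5) * cs;
      for (int k = 0; k < nobs; ++k) {
        d2[k] = (obs_x[k] - tx) * (obs_x[k] - tx) +
                (obs_y[k] - ty) * (obs_y[k] - ty);
        ord[k] = k;
      }
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return d2[a] < d2[b]; });
      for (int k : ord) {
        if (limited && d2[k] > md2) break;
        if (g.los(obs_x[k], obs_y[k], obs_h[k], tx, ty, target_h)) {
          vis(i, j) = 1;
          break;
        }
      }
    }
  }
  return vis;
}
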