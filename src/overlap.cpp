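#include <Rcpp.h>
using namespace Rcpp;

// Count foreground pixel centres that fall inside a transformed model region.
//
// The model region is tabulated on a uniform x-grid in model units as a pair
// of branch curves (ylo[i], yup[i]); a point (u, v) lies inside when
// ylo(k) <= v <= yup(k) at the nearest grid node k (the grid is fine enough
// that nearest-node lookup is below pixel quantization). Nodes where the
// region is empty carry sentinels (ylo = +big, yup = -big) so the interval
// test fails without branching. The similarity transform maps model
// coordinates to pixel coordinates: (x, y) = s * R(theta) * (u, v) +
// (tx, ty); pixels are mapped back through its inverse.
// [[Rcpp::export]]
double overlap_count(NumericVector px, NumericVector py,
                     double s, double tx, double ty, double theta,
                     double x0, double dx,
                     NumericVector ylo, NumericVector yup) {
  const int n = px.size(), m = ylo.size();
  const double ct = std::cos(theta), st = std::sin(theta), inv = 1.0 / s;
  const double invdx = 1.0 / dx;
  const double *lo = ylo.begin(), *up = yup.begin();
  long count = 0;
  for (int i = 0; i < n; ++i) {
    const double rx = px[i] - tx, ry = py[i] - ty;
    const double u = ( ct * rx + st * ry) * inv;
    const double v = (-st * rx + ct * ry) * inv;
    const int k = (int)((u - x0) * invdx + 0.5);
    if ((unsigned)k < (unsigned)m)
      count += (v >= lo[k]) & (v <= up[k]);
  }
  return (double)count;
}

// Even-odd scanline fill of a closed polygon onto a pixel grid.
// Vertices are in pixel coordinates (x right, y up); pixel (row i, col j) of
// the nrow x ncol output has centre (j - 0.5, nrow - i + 0.5). Returns an
// integer matrix of 0/1.
// [[Rcpp::export]]
IntegerMatrix fill_polygon(NumericVector vx, NumericVector vy,
                           int nrow, int ncol) {
  IntegerMatrix out(nrow, ncol);
  const int ne = vx.size() - 1; // closed: last vertex repeats the first
  std::vector<double> xs;
  xs.reserve(16);
  for (int i = 0; i < nrow; ++i) {
    const double y = nrow - i - 0.5; // centre of 0-based row i (top row has largest y)
    xs.clear();
    for (int e = 0; e < ne; ++e) {
      const double y1 = vy[e], y2 = vy[e + 1];
      if ((y1 > y) != (y2 > y)) {
        const double t = (y - y1) / (y2 - y1);
        xs.push_back(vx[e] + t * (vx[e + 1] - vx[e]));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int j0 = (int)std::ceil(xs[k] - 0.5);
      int j1 = (int)std::floor(xs[k + 1] - 0.5 - 1e-12);
      if (j0 < 0) j0 = 0;
      if (j1 > ncol - 1) j1 = ncol - 1;
      for (int j = j0; j <= j1; ++j) out(i, j) = 1;
    }
  }
  return out;
}
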