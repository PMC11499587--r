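#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a logical matrix, 4-connectivity.
// Returns an integer matrix of labels (0 = background), labels 1..k
// assigned in raster-scan order of first encounter, so labeling is
// deterministic and independent of any RNG state.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qi, qj;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      while (!qi.empty()) {
        int ci = qi.back(), cj = qj.back();
        qi.pop_back(); qj.pop_back();
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Fill interior holes of a binary mask: background pixels not reachable
// from the border (4-connectivity over background) become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> qi, qj;
  auto push = [&](int i, int j) {
    size_t idx = (size_t)j * nr + i;
    if (!outside[idx] && !mask(i, j)) {
      outside[idx] = 1;
      qi.push_back(i); qj.push_back(j);
    }
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  while (!qi.empty()) {
    int ci = qi.back(), cj = qj.back();
    qi.pop_back(); qj.pop_back();
    if (ci > 0) push(ci - 1, cj);
    if (ci < nr - 1) push(ci + 1, cj);
    if (cj > 0) push(ci, cj - 1);
    if (cj < nc - 1) push(ci, cj + 1);
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside[(size_t)j * nr + i];
  return out;
}

// Inverse-map affine warp with bilinear interpolation.
// minv is the 2x3 affine mapping OUTPUT pixel coordinates (x, y) to INPUT
// coordinates, in the continuous convention where pixel (x, y) has center
// (x + 0.5, y + 0.5). Out-of-bounds samples take `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, const NumericMatrix& minv,
                              int out_h, int out_w, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double a = minv(0, 0), b = minv(0, 1), tx = minv(0, 2);
  const double c = minv(1, 0), d = minv(1, 1), ty = minv(1, 2);
  for (int xo = 0; xo < out_w; ++xo) {
    const double xc = xo + 0.5;
    for (int yo = 0; yo < out_h; ++yo) {
      const double yc = yo + 0.5;
      const double xi = a * xc + b * yc + tx - 0.5;
      const double yi = c * xc + d * yc + ty - 0.5;
      const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      const double fx = xi - x0, fy = yi - y0;
      double acc = 0.0, wsum = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        for (int dx = 0; dx <= 1; ++dx) {
          const int xs = x0 + dx, ys = y0 + dy;
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
          if (w <= 0) continue;
          if (xs >= 0 && xs < nc && ys >= 0 && ys < nr) {
            acc += w * img(ys, xs);
            wsum += w;
          }
        }
      }
      out(yo, xo) = (wsum > 0) ? (acc + (1.0 - wsum) * fill) : fill;
    }
  }
  return out;
}

// Clipped box-filter sum: out(i, j) = sum of m over the window
// [i - r, i + r] x [j - r, j + r] intersected with the matrix.
// [[Rcpp::export]]
NumericMatrix cpp_box_sum(const LogicalMatrix& m, int r) {
  const int nr = m.nrow(), nc = m.ncol();
  // integral image, (nr + 1) x (nc + 1)
  std::vector<double> s((size_t)(nr + 1) * (nc + 1), 0.0);
  for (int j = 0; j < nc; ++j) {
    double col_acc = 0.0;
    for (int i = 0; i < nr; ++i) {
      col_acc += m(i, j) ? 1.0 : 0.0;
      s[(size_t)(j + 1) * (nr + 1) + (i + 1)] =
        s[(size_t)j * (nr + 1) + (i + 1)] + col_acc;
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int j1 = std::max(j - r, 0), j2 = std::min(j + r, nc - 1);
    for (int i = 0; i < nr; ++i) {
      const int i1 = std::max(i - r, 0), i2 = std::min(i + r, nr - 1);
      out(i, j) = s[(size_t)(j2 + 1) * (nr + 1) + (i2 + 1)]
                - s[(size_t)j1 * (nr + 1) + (i2 + 1)]
                - s[(size_t)(j2 + 1) * (nr + 1) + i1]
                + s[(size_t)j1 * (nr + 1) + i1];
    }
  }
  return out;
}

// Even-odd scanline rasterization of a polygon into an h x w logical mask.
// Pixel (x, y) (0-based, mask column x + 1, row y + 1) is set when its
// center (x + 0.5, y + 0.5) lies inside the polygon under the even-odd
// rule; half-open pixel convention follows from testing centers.
// px, py are polygon vertices in the same pixel coordinate system.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(const NumericVector& px, const NumericVector& py,
                                    int h, int w) {
  LogicalMatrix out(h, w);
  const int n = px.size();
  if (n < 3) return out;
  std::vector<double> xs;
  for (int y = 0; y < h; ++y) {
    const double yc = y + 0.5;
    xs.clear();
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = py[i], y2 = py[j];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        const double t = (yc - y1) / (y2 - y1);
        xs.push_back(px[i] + t * (px[j] - px[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int x0 = (int)std::ceil(xs[k] - 0.5);
      int x1 = (int)std::floor(xs[k + 1] - 0.5);
      if (x0 < 0) x0 = 0;
      if (x1 > w - 1) x1 = w - 1;
      for (int x = x0; x <= x1; ++x) out(y, x) = true;
    }
  }
  return out;
}

// Per-component pixel statistics for a label image: area, bounding box
// (0-based half-open), and centroid of pixel centers.
// [[Rcpp::export]]
List cpp_component_stats(const IntegerMatrix& lab, int n_components) {
  std::vector<double> area(n_components, 0), sx(n_components, 0), sy(n_components, 0);
  std::vector<int> xmin(n_components, INT_MAX), ymin(n_components, INT_MAX),
      xmax(n_components, -1), ymax(n_components, -1);
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (l <= 0) continue;
      const int k = l - 1;
      area[k] += 1;
      sx[k] += j + 0.5;
      sy[k] += i + 0.5;
      if (j < xmin[k]) xmin[k] = j;
      if (j > xmax[k]) xmax[k] = j;
      if (i < ymin[k]) ymin[k] = i;
      if (i > ymax[k]) ymax[k] = i;
    }
  }
  NumericVector A(n_components), CX(n_components), CY(n_components);
  IntegerVector X0(n_components), Y0(n_components), X1(n_components), Y1(n_components);
  for (int k = 0; k < n_components; ++k) {
    A[k] = area[k];
    CX[k] = area[k] > 0 ? sx[k] / area[k] : NA_REAL;
    CY[k] = area[k] > 0 ? sy[k] / area[k] : NA_REAL;
    X0[k] = xmin[k]; Y0[k] = ymin[k];
    X1[k] = xmax[k] + 1; Y1[k] = ymax[k] + 1;
  }
  return List::create(_["area"] = A, _["cx"] = CX, _["cy"] = CY,
                      _["xmin"] = X0, _["ymin"] = Y0, _["xmax"] = X1, _["ymax"] = Y1);
}
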