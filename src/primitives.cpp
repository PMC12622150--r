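// Low-level image primitives used by the segmentation / linking pipelines.
// All arrays follow R's column-major layout with dim = (ny, nx) for slices
// and dim = (ny, nx, nz) for stacks; linear indices are 0-based here and
// converted to 1-based on the R side where needed.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- separable convolution ------------------------------------------------

// Convolve along one dimension of a 3D array with clamp (replicate) padding.
// Lines along the chosen dimension are gathered into a contiguous buffer so
// the inner product runs branch-free except at the clamped edges.
static void conv_dim(const std::vector<double>& in, std::vector<double>& out,
                     int ny, int nx, int nz, const NumericVector& k, int dim) {
  int kr = (k.size() - 1) / 2;
  int nd = (dim == 0) ? ny : (dim == 1) ? nx : nz;
  size_t stride = (dim == 0) ? 1 : (dim == 1) ? (size_t)ny
                                              : (size_t)ny * nx;
  std::vector<double> line(nd), res(nd);
  const double* kp = &k[0];
  int n1 = (dim == 0) ? nx : ny; // the two orthogonal extents
  int n2 = (dim == 0) ? nz : (dim == 1) ? nz : nx;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      size_t base;
      if (dim == 0) base = (size_t)ny * a + (size_t)ny * nx * b;
      else if (dim == 1) base = (size_t)a + (size_t)ny * nx * b;
      else base = (size_t)a + (size_t)ny * b;
      const double* src = &in[base];
      for (int p = 0; p < nd; ++p) line[p] = src[stride * p];
      for (int p = 0; p < nd; ++p) {
        double acc = 0.0;
        if (p >= kr && p + kr < nd) {
          const double* lp = &line[p - kr];
          int m = 2 * kr + 1;
          for (int t = 0; t < m; ++t) acc += kp[t] * lp[t];
        } else {
          for (int t = -kr; t <= kr; ++t) {
            int q = p + t;
            if (q < 0) q = 0;
            if (q >= nd) q = nd - 1;
            acc += kp[t + kr] * line[q];
          }
        }
        res[p] = acc;
      }
      double* dst = &out[base];
      for (int p = 0; p < nd; ++p) dst[stride * p] = res[p];
    }
  }
}

// [[Rcpp::export(name = ".conv_sep3d")]]
NumericVector conv_sep3d(NumericVector arr, IntegerVector dims,
                         NumericVector ky, NumericVector kx, NumericVector kz) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  const std::vector<double>* src = &a;
  std::vector<double>* dst = &b;
  bool flipped = false;
  NumericVector ks[3] = {ky, kx, kz};
  for (int d = 0; d < 3; ++d) {
    if (ks[d].size() <= 1) continue;
    conv_dim(*src, *dst, ny, nx, nz, ks[d], d);
    std::swap(a, b); // result always ends in a
    (void)flipped;
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---- connected components -------------------------------------------------

// 2D labelling, 4- or 8-connectivity, labels assigned in raster-scan
// discovery order so the result is deterministic and label-permutation free.
// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerMatrix cc_label_2d(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(std::make_pair(y, x));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int n = 0; n < nnb; ++n) {
          int yy = p.first + dy8[n], xx = p.second + dx8[n];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

// 3D labelling with 26-connectivity (independent route used as the oracle
// for the slice-linking algorithm, and for whole-stack masks).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  size_t n = (size_t)ny * nx * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int z = p / ((size_t)ny * nx);
      int rem = p % ((size_t)ny * nx);
      int x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dz && !dx && !dy) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 ||
                zz >= nz)
              continue;
            size_t q = (size_t)yy + (size_t)ny * xx + (size_t)ny * nx * zz;
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- grayscale disk morphology (for top-hat foci detection) ---------------

// [[Rcpp::export(name = ".gray_morph_disk")]]
NumericMatrix gray_morph_disk(NumericMatrix img, double radius, bool dilate) {
  int ny = img.nrow(), nx = img.ncol();
  int r = (int)std::ceil(radius);
  std::vector<int> oy, ox;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if ((double)dy * dy + (double)dx * dx <= radius * radius + 1e-9) {
        oy.push_back(dy);
        ox.push_back(dx);
      }
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (size_t k = 0; k < oy.size(); ++k) {
        int yy = y + oy[k], xx = x + ox[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double u = img(yy, xx);
        if (dilate ? (u > v) : (u < v)) v = u;
      }
      out(y, x) = v;
    }
  return out;
}

// ---- chamfer distance + watershed (optional split of touching nuclei) -----

// 3-4 chamfer distance (scaled by 1/3) from each foreground pixel to the
// nearest background pixel.
// [[Rcpp::export(name = ".chamfer_dist_2d")]]
NumericMatrix chamfer_dist_2d(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  double big = 1e9;
  NumericMatrix d(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) d(y, x) = mask(y, x) ? big : 0.0;
  // forward pass
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (d(y, x) == 0) continue;
      double v = d(y, x);
      if (y > 0) v = std::min(v, d(y - 1, x) + 3);
      if (x > 0) v = std::min(v, d(y, x - 1) + 3);
      if (y > 0 && x > 0) v = std::min(v, d(y - 1, x - 1) + 4);
      if (y < ny - 1 && x > 0) v = std::min(v, d(y + 1, x - 1) + 4);
      // off-image counts as background
      if (y == 0 || x == 0) v = std::min(v, 3.0);
      d(y, x) = v;
    }
  // backward pass
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y) {
      if (d(y, x) == 0) continue;
      double v = d(y, x);
      if (y < ny - 1) v = std::min(v, d(y + 1, x) + 3);
      if (x < nx - 1) v = std::min(v, d(y, x + 1) + 3);
      if (y < ny - 1 && x < nx - 1) v = std::min(v, d(y + 1, x + 1) + 4);
      if (y > 0 && x < nx - 1) v = std::min(v, d(y - 1, x + 1) + 4);
      if (y == ny - 1 || x == nx - 1) v = std::min(v, 3.0);
      d(y, x) = v;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) d(y, x) /= 3.0;
  return d;
}

struct WsNode {
  double prio;
  long order;
  int y, x, label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Marker-based priority-flood watershed restricted to `mask`; `prio` is the
// flooding priority (lower floods first; pass -distance to split on ridges).
// [[Rcpp::export(name = ".watershed_2d")]]
IntegerMatrix watershed_2d(NumericMatrix prio, IntegerMatrix markers,
                           LogicalMatrix mask) {
  int ny = prio.nrow(), nx = prio.ncol();
  IntegerMatrix lab(ny, nx);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (markers(y, x) > 0 && mask(y, x)) {
        lab(y, x) = markers(y, x);
        WsNode n = {prio(y, x), order++, y, x, markers(y, x)};
        pq.push(n);
      }
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    for (int k = 0; k < 4; ++k) {
      int yy = n.y + dy[k], xx = n.x + dx[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (!mask(yy, xx) || lab(yy, xx) != 0) continue;
      lab(yy, xx) = n.label;
      WsNode m = {prio(yy, xx), order++, yy, xx, n.label};
      pq.push(m);
    }
  }
  return lab;
}

// ---- 3D binary dilation with an ellipsoidal kernel ------------------------

// [[Rcpp::export(name = ".dilate_mask_3d")]]
LogicalVector dilate_mask_3d(LogicalVector mask, IntegerVector dims, int ry,
                             int rx, int rz) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  size_t n = (size_t)ny * nx * nz;
  std::vector<int> oy, ox, oz;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dx = -rx; dx <= rx; ++dx)
      for (int dy = -ry; dy <= ry; ++dy) {
        double e = 0;
        if (ry > 0) e += (double)dy * dy / ((double)ry * ry);
        else if (dy != 0) continue;
        if (rx > 0) e += (double)dx * dx / ((double)rx * rx);
        else if (dx != 0) continue;
        if (rz > 0) e += (double)dz * dz / ((double)rz * rz);
        else if (dz != 0) continue;
        if (e <= 1.0 + 1e-9) {
          oy.push_back(dy);
          ox.push_back(dx);
          oz.push_back(dz);
        }
      }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = i / ((size_t)ny * nx);
    int rem = i % ((size_t)ny * nx);
    int x = rem / ny, y = rem % ny;
    for (size_t k = 0; k < oy.size(); ++k) {
      int yy = y + oy[k], xx = x + ox[k], zz = z + oz[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      out[(size_t)yy + (size_t)ny * xx + (size_t)ny * nx * zz] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}
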