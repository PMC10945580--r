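// Low-level voxel operations shared by the feature bank, morphology and
// connected-component code. All volumes use (z, y, x) axis order with the
// usual R column-major layout: idx = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

static void get_dims(const RObject& v, int& nz, int& ny, int& nx) {
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

static std::vector<double> gauss_kernel(double sigma) {
  int h = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * h + 1);
  double s = 0.0;
  for (int k = -h; k <= h; ++k) {
    w[k + h] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += w[k + h];
  }
  for (double& x : w) x /= s;
  return w;
}

// Separable in-plane (per z-slice) Gaussian blur, reflected boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss2d(NumericVector vol, double sigma) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  std::vector<double> w = gauss_kernel(sigma);
  int h = ((int)w.size() - 1) / 2;
  NumericVector tmp(vol.size()), out(vol.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        for (int k = -h; k <= h; ++k)
          s += w[k + h] * vol[vidx(z, refl(y + k, ny), x, nz, ny)];
        tmp[vidx(z, y, x, nz, ny)] = s;
      }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        for (int k = -h; k <= h; ++k)
          s += w[k + h] * tmp[vidx(z, y, refl(x + k, nx), nz, ny)];
        out[vidx(z, y, x, nz, ny)] = s;
      }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// In-plane 5-point Laplacian, reflected boundaries (zero on flat fields).
// [[Rcpp::export]]
NumericVector cpp_laplace2d(NumericVector vol) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  NumericVector out(vol.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double c = vol[vidx(z, y, x, nz, ny)];
        double s = vol[vidx(z, refl(y - 1, ny), x, nz, ny)] +
                   vol[vidx(z, refl(y + 1, ny), x, nz, ny)] +
                   vol[vidx(z, y, refl(x - 1, nx), nz, ny)] +
                   vol[vidx(z, y, refl(x + 1, nx), nz, ny)] - 4.0 * c;
        out[vidx(z, y, x, nz, ny)] = s;
      }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// In-plane Sobel gradient magnitude per z-slice.
// [[Rcpp::export]]
NumericVector cpp_sobel_mag(NumericVector vol) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  NumericVector out(vol.size());
  const int ky[3] = {-1, 0, 1};
  const double wx[3] = {1.0, 2.0, 1.0};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double gx = 0.0, gy = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) {
            double v = vol[vidx(z, refl(y + ky[a], ny), refl(x + ky[b], nx), nz, ny)];
            gy += (double)ky[a] * wx[b] * v;  // d/dy
            gx += (double)ky[b] * wx[a] * v;  // d/dx
          }
        out[vidx(z, y, x, nz, ny)] = std::sqrt(gx * gx + gy * gy);
      }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// 3x3x3 local mean and population standard deviation, reflected boundaries.
// [[Rcpp::export]]
List cpp_box_mean_sd(NumericVector vol) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  NumericVector mu(vol.size()), sd(vol.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0, s2 = 0.0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              double v = vol[vidx(refl(z + dz, nz), refl(y + dy, ny), refl(x + dx, nx), nz, ny)];
              s += v; s2 += v * v;
            }
        double m = s / 27.0;
        double var = s2 / 27.0 - m * m;
        mu[vidx(z, y, x, nz, ny)] = m;
        sd[vidx(z, y, x, nz, ny)] = var > 0 ? std::sqrt(var) : 0.0;
      }
  mu.attr("dim") = vol.attr("dim");
  sd.attr("dim") = vol.attr("dim");
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Grayscale erosion (min filter) with a 3x3x3 structuring element.
// [[Rcpp::export]]
NumericVector cpp_erode_gray(NumericVector vol) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  NumericVector out(vol.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double m = R_PosInf;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              double v = vol[vidx(refl(z + dz, nz), refl(y + dy, ny), refl(x + dx, nx), nz, ny)];
              if (v < m) m = v;
            }
        out[vidx(z, y, x, nz, ny)] = m;
      }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// Iterated binary dilation/erosion with a 3x3x3 (or in-plane 1x3x3) element.
static LogicalVector morph_binary(LogicalVector vol, int iter, bool planar, bool dilate) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  LogicalVector cur = clone(vol);
  int zr = planar ? 0 : 1;
  for (int it = 0; it < iter; ++it) {
    LogicalVector nxt(cur.size());
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          bool acc = dilate ? false : true;
          for (int dz = -zr; dz <= zr && (dilate ? !acc : acc); ++dz)
            for (int dy = -1; dy <= 1 && (dilate ? !acc : acc); ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int zz = z + dz, yy = y + dy, xx = x + dx;
                bool v;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  v = false;  // outside volume counts as background
                else
                  v = cur[vidx(zz, yy, xx, nz, ny)];
                if (dilate) { if (v) { acc = true; break; } }
                else { if (!v) { acc = false; break; } }
              }
          nxt[vidx(z, y, x, nz, ny)] = acc;
        }
    cur = nxt;
  }
  cur.attr("dim") = vol.attr("dim");
  return cur;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_binary(LogicalVector vol, int iter, bool planar) {
  return morph_binary(vol, iter, planar, true);
}

// [[Rcpp::export]]
LogicalVector cpp_erode_binary(LogicalVector vol, int iter, bool planar) {
  return morph_binary(vol, iter, planar, false);
}

// Connected-component labelling under 6/18/26-connectivity (iterative BFS).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vol, int connectivity) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs.push_back({dz, dy, dx});
      }
  IntegerVector lab(vol.size());
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        if (!vol[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t j = stack.back(); stack.pop_back();
          int zz = (int)(j % nz);
          int rest = (int)(j / nz);
          int yy = rest % ny;
          int xx = rest / ny;
          for (const auto& o : offs) {
            int z2 = zz + o[0], y2 = yy + o[1], x2 = xx + o[2];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
            R_xlen_t k = vidx(z2, y2, x2, nz, ny);
            if (vol[k] && lab[k] == 0) { lab[k] = next; stack.push_back(k); }
          }
        }
      }
  lab.attr("dim") = vol.attr("dim");
  return lab;
}

// Union of Euclidean balls stamped at given (z,y,x) centers: tube rendering.
// [[Rcpp::export]]
LogicalVector cpp_stamp_balls(IntegerVector dim, NumericMatrix centers, NumericVector radii) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  for (int i = 0; i < centers.nrow(); ++i) {
    double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    double r = radii[radii.size() == 1 ? 0 : i];
    double r2 = r * r;
    int z0 = std::max(0, (int)std::floor(cz - r)), z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    int y0 = std::max(0, (int)std::floor(cy - r)), y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    int x0 = std::max(0, (int)std::floor(cx - r)), x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double dz = z - cz, dy = y - cy, dx = x - cx;
          if (dz * dz + dy * dy + dx * dx <= r2)
            out[vidx(z, y, x, nz, ny)] = true;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Minimum Euclidean distance from each query point to a point set (voxel units).
// [[Rcpp::export]]
NumericVector cpp_min_dist_points(NumericMatrix query, NumericMatrix pts) {
  NumericVector out(query.nrow());
  for (int i = 0; i < query.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < pts.nrow(); ++j) {
      double dz = query(i, 0) - pts(j, 0);
      double dy = query(i, 1) - pts(j, 1);
      double dx = query(i, 2) - pts(j, 2);
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
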