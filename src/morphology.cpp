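// 3-D binary image kernels used by the lung segmentation stage:
// connected-component labeling (26- or 6-connectivity), flood fill of the
// background from the grid boundary (hole filling), and the squared
// Euclidean distance transform (Felzenszwalb & Huttenlocher lower-envelope
// scan, one separable pass per axis) on which ball-structuring-element
// dilation and erosion are built.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// dims are (nz, ny, nx); arrays are stored R-style column-major with z
// fastest, i.e. linear index = z + nz*(y + ny*x).

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const IntegerVector& dims,
                          const int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  int next = 0;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = lin(z0, y0, x0, nz, ny);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int z = i % nz, r = i / nz;
          int y = r % ny, x = r / ny;
          for (int k = 0; k < nn; ++k) {
            int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// Marks every background (false) voxel reachable from the grid boundary via
// 6-connectivity. Used for hole filling: holes are the unmarked background.
// [[Rcpp::export]]
LogicalVector cpp_background_from_boundary(const LogicalVector& mask,
                                           const IntegerVector& dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  LogicalVector reach(n, false);
  std::vector<int> stack;
  stack.reserve(4096);

  auto push = [&](int z, int y, int x) {
    int i = lin(z, y, x, nz, ny);
    if (!mask[i] && !reach[i]) { reach[i] = true; stack.push_back(i); }
  };
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) { push(0, y, x); push(nz - 1, y, x); }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) { push(z, 0, x); push(z, ny - 1, x); }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) { push(z, y, 0); push(z, y, nx - 1); }

  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int z = i % nz, r = i / nz;
    int y = r % ny, x = r / ny;
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      push(zz, yy, xx);
    }
  }
  return reach;
}

// 1-D squared-distance lower envelope, applied in place along each axis.
static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from each voxel to the nearest
// voxel where `feature` is true. Voxels inside the feature set get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(const LogicalVector& feature,
                         const IntegerVector& dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const double INF = 1e18;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int base = lin(0, y, x, nz, ny);
      for (int z = 0; z < nz; ++z) f[z] = out[base + z];
      edt_1d(f, d, v, zb, nz);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[lin(z, y, x, nz, ny)];
      edt_1d(f, d, v, zb, ny);
      for (int y = 0; y < ny; ++y) out[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[lin(z, y, x, nz, ny)];
      edt_1d(f, d, v, zb, nx);
      for (int x = 0; x < nx; ++x) out[lin(z, y, x, nz, ny)] = d[x];
    }
  return out;
}
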