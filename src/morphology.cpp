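#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Grid convention shared with the R layer: linear index = i + nx*(j + ny*k),
// 0-based in C++, coordinate of (i,j,k) = origin + h*(i,j,k).

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Mark every grid point p with ||p - pos[a]|| <= radii[a] for some a.
// Serves both vdW occupancy (radii = vdw) and the blocked-center field
// (radii = vdw + probe): a probe center is valid iff strictly farther than
// vdw + probe from every atom, i.e. iff NOT marked here.
// [[Rcpp::export]]
LogicalVector cpp_mark_spheres(IntegerVector dims, NumericVector origin,
                               double h, NumericMatrix pos,
                               NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::fill(out.begin(), out.end(), FALSE);
  const int na = pos.nrow();
  for (int a = 0; a < na; ++a) {
    const double ax = pos(a, 0), ay = pos(a, 1), az = pos(a, 2);
    const double r = radii[a], r2 = r * r;
    // conservative integer bounding box; exact test is inside the loop
    int i0 = (int)std::floor((ax - r - origin[0]) / h) - 1;
    int i1 = (int)std::ceil((ax + r - origin[0]) / h) + 1;
    int j0 = (int)std::floor((ay - r - origin[1]) / h) - 1;
    int j1 = (int)std::ceil((ay + r - origin[1]) / h) + 1;
    int k0 = (int)std::floor((az - r - origin[2]) / h) - 1;
    int k1 = (int)std::ceil((az + r - origin[2]) / h) + 1;
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + h * k - az, dz2 = dz * dz;
      if (dz2 > r2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + h * j - ay, d2yz = dy * dy + dz2;
        if (d2yz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + h * i - ax;
          if (dx * dx + d2yz <= r2) out[lin(i, j, k, nx, ny)] = TRUE;
        }
      }
    }
  }
  return out;
}

// Large finite sentinel standing in for "no feature point": keeps the
// parabola intersections finite (INF - INF would be NaN) while staying far
// above any real squared lattice distance and exactly representable.
static const double DT_EMPTY = 1e12;

// 1D squared distance transform (Felzenszwalb & Huttenlocher), exact for
// integer-valued inputs. f/d/v/z are scratch of length >= n (+1 for z).
static void dt1d(const double *f, double *d, int *v, double *z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in grid-index units) from every grid
// point to the nearest TRUE point of `field`. Values >= 1e12 mean "no
// feature point anywhere" (empty field).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector field, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = field[t] ? 0.0 : DT_EMPTY;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = lin(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), dd.data(), v.data(), z.data(), nx);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[lin(i, j, k, nx, ny)];
      dt1d(f.data(), dd.data(), v.data(), z.data(), ny);
      for (int j = 0; j < ny; ++j) d[lin(i, j, k, nx, ny)] = dd[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[lin(i, j, k, nx, ny)];
      dt1d(f.data(), dd.data(), v.data(), z.data(), nz);
      for (int k = 0; k < nz; ++k) d[lin(i, j, k, nx, ny)] = dd[k];
    }
  return d;
}

// 26-connected component labeling by iterative flood fill (explicit stack;
// recursion depth would be unbounded on million-point cavities).
// Returns 0 for clear points, 1..L for components, in first-encounter order
// scanning i fastest.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector field, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!field[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t q = lin(ii, jj, kk, nx, ny);
            if (field[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Exposed voxel faces per label: a face counts when the 6-neighbor across it
// carries a different label (or lies outside the grid). Area = h^2 * count.
// [[Rcpp::export]]
IntegerVector cpp_face_counts(IntegerVector lab, IntegerVector dims,
                              int nlabels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector cnt(nlabels);
  std::fill(cnt.begin(), cnt.end(), 0);
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int L = lab[lin(i, j, k, nx, ny)];
        if (L == 0) continue;
        for (int f = 0; f < 6; ++f) {
          const int ii = i + off[f][0], jj = j + off[f][1], kk = k + off[f][2];
          int Ln = 0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            Ln = lab[lin(ii, jj, kk, nx, ny)];
          if (Ln != L) ++cnt[L - 1];
        }
      }
  return cnt;
}

// Per-row minimum squared distance from pos (m x 3) to pts (n x 3).
// [[Rcpp::export]]
NumericVector cpp_min_dist2(NumericMatrix pos, NumericMatrix pts) {
  const int m = pos.nrow(), n = pts.nrow();
  NumericVector out(m);
  for (int a = 0; a < m; ++a) {
    double best = std::numeric_limits<double>::infinity();
    const double ax = pos(a, 0), ay = pos(a, 1), az = pos(a, 2);
    for (int p = 0; p < n; ++p) {
      const double dx = pts(p, 0) - ax, dy = pts(p, 1) - ay,
                   dz = pts(p, 2) - az;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = best;
  }
  return out;
}
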