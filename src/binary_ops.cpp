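// Binary volume operations: hysteresis thresholding, 26-connected
// labeling, ball-neighborhood majority (median) filtering, squared
// Euclidean distance transform and local thickness.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 26-neighborhood offsets, built once per call.
static void neigh26(const int* d, std::vector<long>& off,
                    std::vector<int>& dx, std::vector<int>& dy,
                    std::vector<int>& dz) {
  long sx = 1, sy = d[0], sz = (long)d[0] * d[1];
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        off.push_back(x * sx + y * sy + z * sz);
        dx.push_back(x); dy.push_back(y); dz.push_back(z);
      }
}

static inline void idx_to_xyz(long i, const int* d, int& x, int& y, int& z) {
  x = (int)(i % d[0]);
  y = (int)((i / d[0]) % d[1]);
  z = (int)(i / ((long)d[0] * d[1]));
}

// Seeds: vol >= thigh; growth: 26-connected through vol >= tlow.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalVector hysteresis_cpp(NumericVector vol, IntegerVector dim,
                             double tlow, double thigh) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  std::vector<long> off; std::vector<int> dx, dy, dz;
  neigh26(d, off, dx, dy, dz);
  std::vector<unsigned char> out(n, 0);
  std::vector<long> stack;
  for (long i = 0; i < n; ++i)
    if (vol[i] >= thigh && !out[i]) { out[i] = 1; stack.push_back(i); }
  while (!stack.empty()) {
    long i = stack.back(); stack.pop_back();
    int x, y, z; idx_to_xyz(i, d, x, y, z);
    for (size_t k = 0; k < off.size(); ++k) {
      int nx_ = x + dx[k], ny_ = y + dy[k], nz_ = z + dz[k];
      if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= d[0] || ny_ >= d[1] || nz_ >= d[2])
        continue;
      long j = i + off[k];
      if (!out[j] && vol[j] >= tlow) { out[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector res(n);
  for (long i = 0; i < n; ++i) res[i] = (out[i] != 0);
  return res;
}

// 26-connected component labeling; labels 1..k in discovery order,
// background 0.
// [[Rcpp::export(name = ".label_cpp")]]
IntegerVector label_cpp(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  std::vector<long> off; std::vector<int> dx, dy, dz;
  neigh26(d, off, dx, dy, dz);
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      long i = stack.back(); stack.pop_back();
      int x, y, z; idx_to_xyz(i, d, x, y, z);
      for (size_t k = 0; k < off.size(); ++k) {
        int nx_ = x + dx[k], ny_ = y + dy[k], nz_ = z + dz[k];
        if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= d[0] || ny_ >= d[1] || nz_ >= d[2])
          continue;
        long j = i + off[k];
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Majority vote over the Euclidean ball of given radius (voxels outside
// the volume count as background, so surfaces erode slightly at the
// image border, as with zero padding).
// [[Rcpp::export(name = ".median_ball_cpp")]]
LogicalVector median_ball_cpp(LogicalVector mask, IntegerVector dim, int radius) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  if (radius < 1) return clone(mask);
  std::vector<int> ox, oy, oz;
  for (int z = -radius; z <= radius; ++z)
    for (int y = -radius; y <= radius; ++y)
      for (int x = -radius; x <= radius; ++x)
        if (x * x + y * y + z * z <= radius * radius) {
          ox.push_back(x); oy.push_back(y); oz.push_back(z);
        }
  int m = (int)ox.size();
  int half = m / 2; // strict majority: count > m/2
  long sx = 1, sy = d[0], sz = (long)d[0] * d[1];
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) {
    int x, y, z; idx_to_xyz(i, d, x, y, z);
    int cnt = 0;
    for (int k = 0; k < m; ++k) {
      int nx_ = x + ox[k], ny_ = y + oy[k], nz_ = z + oz[k];
      if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= d[0] || ny_ >= d[1] || nz_ >= d[2])
        continue;
      if (mask[nx_ * sx + ny_ * sy + nz_ * sz]) ++cnt;
    }
    out[i] = (cnt > half);
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, std::vector<double>& out,
                 std::vector<int>& v, std::vector<double>& zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e20; zbuf[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    out[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from each foreground voxel to
// the nearest background voxel center; 0 on background. Voxels outside
// the volume are treated as background.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  const double INF = 1e18;
  std::vector<double> g(n);
  // pass along x, seeded by the mask plus the implicit background outside:
  // distance to the nearest background within the row, capped later by
  // the out-of-bounds background via the border formula.
  long sy = d[0], sz = (long)d[0] * d[1];
  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<double> f(nmax), o(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  for (long i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  // x pass
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y) {
      long base = y * sy + z * sz;
      for (int x = 0; x < d[0]; ++x) f[x] = g[base + x];
      dt1d(f, o, v, zbuf, d[0]);
      for (int x = 0; x < d[0]; ++x) {
        // implicit background just outside the row ends
        double border = std::min((double)(x + 1) * (x + 1),
                                 (double)(d[0] - x) * (d[0] - x));
        g[base + x] = std::min(o[x], border);
      }
    }
  // y pass
  for (int z = 0; z < d[2]; ++z)
    for (int x = 0; x < d[0]; ++x) {
      long base = x + z * sz;
      for (int y = 0; y < d[1]; ++y) f[y] = g[base + y * sy];
      dt1d(f, o, v, zbuf, d[1]);
      for (int y = 0; y < d[1]; ++y) {
        double border = std::min((double)(y + 1) * (y + 1),
                                 (double)(d[1] - y) * (d[1] - y));
        g[base + y * sy] = std::min(o[y], border);
      }
    }
  // z pass
  for (int y = 0; y < d[1]; ++y)
    for (int x = 0; x < d[0]; ++x) {
      long base = x + y * sy;
      for (int z = 0; z < d[2]; ++z) f[z] = g[base + z * sz];
      dt1d(f, o, v, zbuf, d[2]);
      for (int z = 0; z < d[2]; ++z) {
        double border = std::min((double)(z + 1) * (z + 1),
                                 (double)(d[2] - z) * (d[2] - z));
        g[base + z * sz] = std::min(o[z], border);
      }
    }
  NumericVector res(g.begin(), g.end());
  return res;
}

// Local thickness: every object voxel receives the diameter of the
// largest inscribed sphere containing it. Computed by painting, for each
// object voxel c with inscribed radius r(c) = sqrt(EDT^2), the value
// 2*r(c) - 1 over the ball of radius r(c) around c (largest first, so
// each voxel keeps the max). The "-1" converts center-to-center distance
// into a surface-to-surface diameter on the voxel grid.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  NumericVector edt = edt_sq_cpp(mask, dim);
  std::vector<std::pair<double, long> > fg;
  for (long i = 0; i < n; ++i)
    if (mask[i]) fg.push_back(std::make_pair(edt[i], i));
  std::sort(fg.begin(), fg.end());
  std::reverse(fg.begin(), fg.end());
  NumericVector th(n, 0.0);
  long sy = d[0], sz = (long)d[0] * d[1];
  for (size_t q = 0; q < fg.size(); ++q) {
    long i = fg[q].second;
    double r = std::sqrt(fg[q].first);
    double diam = 2.0 * r - 1.0;
    if (diam < 1.0) diam = 1.0;
    int R = (int)std::floor(r);
    int x, y, z; idx_to_xyz(i, d, x, y, z);
    double r2 = r * r;
    for (int zz = std::max(0, z - R); zz <= std::min(d[2] - 1, z + R); ++zz)
      for (int yy = std::max(0, y - R); yy <= std::min(d[1] - 1, y + R); ++yy) {
        double dz2 = (zz - z) * (double)(zz - z);
        double dy2 = (yy - y) * (double)(yy - y);
        if (dz2 + dy2 > r2) continue;
        int xr = (int)std::floor(std::sqrt(r2 - dz2 - dy2));
        long base = yy * sy + zz * sz;
        for (int xx = std::max(0, x - xr); xx <= std::min(d[0] - 1, x + xr); ++xx) {
          long j = base + xx;
          if (mask[j] && th[j] < diam) th[j] = diam;
        }
      }
  }
  return th;
}
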