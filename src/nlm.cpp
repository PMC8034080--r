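// Non-local means denoising of a 3D volume, offset decomposition:
// for each translation within the search window the patchwise squared
// difference is a box filter of the voxelwise squared difference, so the
// whole filter runs in O(search_window * n) instead of
// O(search_window * patch * n). The patch distance is symmetric in the
// offset, so each offset pair (d, -d) is processed once and contributes
// to both endpoints.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// in-place box mean along one axis with edge clamping
static void box_axis(std::vector<float>& a, const int* d, int radius, int axis) {
  int nx = d[0], ny = d[1], nz = d[2];
  long sy = nx, sz = (long)nx * ny;
  int n_axis = d[axis];
  long stride = (axis == 0) ? 1 : (axis == 1) ? sy : sz;
  int n1, n2; long s1, s2;
  if (axis == 0)      { n1 = ny; s1 = sy; n2 = nz; s2 = sz; }
  else if (axis == 1) { n1 = nx; s1 = 1;  n2 = nz; s2 = sz; }
  else                { n1 = nx; s1 = 1;  n2 = ny; s2 = sy; }
  std::vector<float> line(n_axis), out(n_axis);
  float inv = 1.0f / (2 * radius + 1);
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      long base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n_axis; ++i) line[i] = a[base + i * stride];
      float acc = 0.0f;
      for (int k = -radius; k <= radius; ++k) acc += line[clampi(k, n_axis)];
      out[0] = acc * inv;
      for (int i = 1; i < n_axis; ++i) {
        acc += line[clampi(i + radius, n_axis)] - line[clampi(i - radius - 1, n_axis)];
        out[i] = acc * inv;
      }
      for (int i = 0; i < n_axis; ++i) a[base + i * stride] = out[i];
    }
}

// shifted[i] = v[i + (ox,oy,oz)] with edge clamping
static void shift_vol(const std::vector<float>& v, std::vector<float>& out,
                      const int* d, int ox, int oy, int oz) {
  long sy = d[0], sz = (long)d[0] * d[1];
  for (int z = 0; z < d[2]; ++z) {
    int zs = clampi(z + oz, d[2]);
    for (int y = 0; y < d[1]; ++y) {
      int ys = clampi(y + oy, d[1]);
      const float* src = &v[ys * sy + zs * sz];
      float* dst = &out[y * sy + z * sz];
      if (ox >= 0) {
        int nfull = d[0] - ox;
        if (nfull > 0) std::memcpy(dst, src + ox, nfull * sizeof(float));
        for (int x = nfull > 0 ? nfull : 0; x < d[0]; ++x)
          dst[x] = src[d[0] - 1];
      } else {
        int pad = -ox;
        for (int x = 0; x < pad && x < d[0]; ++x) dst[x] = src[0];
        if (d[0] - pad > 0)
          std::memcpy(dst + pad, src, (d[0] - pad) * sizeof(float));
      }
    }
  }
}

// [[Rcpp::export(name = ".nlm_cpp")]]
NumericVector nlm_cpp(NumericVector vol, IntegerVector dim, double h,
                      int patch_r, int search_r) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  std::vector<float> v(n);
  for (long i = 0; i < n; ++i) v[i] = (float)vol[i];
  std::vector<float> num(n), den(n, 1.0f); // zero offset: weight 1, self
  for (long i = 0; i < n; ++i) num[i] = v[i];
  std::vector<float> shifted(n), ssd(n);
  float inv_h2 = 1.0f / (float)(h * h);
  for (int oz = -search_r; oz <= search_r; ++oz)
    for (int oy = -search_r; oy <= search_r; ++oy)
      for (int ox = -search_r; ox <= search_r; ++ox) {
        // half the window: the mirrored offset is handled symmetrically
        if (oz < 0 || (oz == 0 && (oy < 0 || (oy == 0 && ox <= 0)))) continue;
        shift_vol(v, shifted, d, ox, oy, oz);
        for (long i = 0; i < n; ++i) {
          float diff = v[i] - shifted[i];
          ssd[i] = diff * diff;
        }
        box_axis(ssd, d, patch_r, 0);
        box_axis(ssd, d, patch_r, 1);
        box_axis(ssd, d, patch_r, 2);
        for (long i = 0; i < n; ++i) {
          float w = std::exp(-ssd[i] * inv_h2);
          num[i] += w * shifted[i];
          den[i] += w;
        }
        // mirrored contribution for the opposite offset, restricted to
        // voxel pairs that are both inside the volume (the linear index
        // must not wrap across rows or slices)
        long off = (long)ox + (long)oy * d[0] + (long)oz * d[0] * d[1];
        int x0 = std::max(0, -ox), x1 = std::min(d[0], d[0] - ox);
        int y0 = std::max(0, -oy), y1 = std::min(d[1], d[1] - oy);
        int z0 = std::max(0, -oz), z1 = std::min(d[2], d[2] - oz);
        for (int z = z0; z < z1; ++z)
          for (int y = y0; y < y1; ++y) {
            long base = (long)y * d[0] + (long)z * d[0] * d[1];
            for (int x = x0; x < x1; ++x) {
              long i = base + x;
              long j = i + off;
              float w = std::exp(-ssd[i] * inv_h2);
              num[j] += w * v[i];
              den[j] += w;
            }
          }
      }
  NumericVector res(n);
  for (long i = 0; i < n; ++i) res[i] = num[i] / den[i];
  return res;
}
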