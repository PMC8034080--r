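// Separable 3D convolution and Hessian-based tubeness response.
//
// Volumes are plain numeric vectors in R column-major order with
// dim = (nx, ny, nz); x is the fastest-varying axis. Boundaries are
// handled by symmetric reflection (mirror about the edge voxel),
// matching the convention of the usual scientific image stacks.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Convolve along one axis (0 = x, 1 = y, 2 = z) with an odd-length kernel.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      const int* d, const std::vector<double>& kernel, int axis) {
  int nx = d[0], ny = d[1], nz = d[2];
  int n_axis = d[axis];
  int radius = ((int)kernel.size() - 1) / 2;
  // strides
  long sx = 1, sy = (long)nx, sz = (long)nx * ny;
  long stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  // iterate over all lines along `axis`
  int n1, n2; long s1, s2;
  if (axis == 0)      { n1 = ny; s1 = sy; n2 = nz; s2 = sz; }
  else if (axis == 1) { n1 = nx; s1 = sx; n2 = nz; s2 = sz; }
  else                { n1 = nx; s1 = sx; n2 = ny; s2 = sy; }
  // each line is copied into a reflection-padded buffer so the inner
  // loop is a plain dot product the compiler can vectorize
  std::vector<double> ext(n_axis + 2 * radius);
  const double* kp = kernel.data();
  int klen = 2 * radius + 1;
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      long base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n_axis; ++i) ext[radius + i] = in[base + i * stride];
      for (int k = 0; k < radius; ++k) {
        ext[radius - 1 - k] = in[base + reflect_idx(-1 - k, n_axis) * stride];
        ext[radius + n_axis + k] = in[base + reflect_idx(n_axis + k, n_axis) * stride];
      }
      for (int i = 0; i < n_axis; ++i) {
        double acc = 0.0;
        const double* ep = ext.data() + i;
        for (int k = 0; k < klen; ++k) acc += kp[k] * ep[k];
        out[base + i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  int d[3] = {dim[0], dim[1], dim[2]};
  std::vector<double> in(vol.begin(), vol.end());
  std::vector<double> out(in.size());
  std::vector<double> k(kernel.begin(), kernel.end());
  conv_axis(in, out, d, k, axis);
  NumericVector res(out.begin(), out.end());
  return res;
}

// Sampled Gaussian and its derivatives, truncated at 4 sigma (the common
// default of scientific image libraries). The 0th-order kernel is
// normalized to unit sum; derivative kernels share the same normalization
// constant so that derivative magnitudes stay consistent.
static std::vector<double> gauss_kernel(double sigma, int order) {
  int radius = (int)(4.0 * sigma + 0.5);
  if (radius < 1) radius = 1;
  std::vector<double> g(2 * radius + 1);
  double s2 = sigma * sigma;
  double sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    double v = std::exp(-0.5 * (double)i * i / s2);
    g[i + radius] = v;
    sum += v;
  }
  for (double& v : g) v /= sum;
  if (order == 1) {
    for (int i = -radius; i <= radius; ++i) g[i + radius] *= -(double)i / s2;
  } else if (order == 2) {
    for (int i = -radius; i <= radius; ++i)
      g[i + radius] *= ((double)i * i - s2) / (s2 * s2);
    // remove the truncation's DC leakage so constant signals give an
    // exactly zero second derivative
    double mean = 0.0;
    for (double v : g) mean += v;
    mean /= g.size();
    for (double& v : g) v -= mean;
  }
  return g;
}

// Eigenvalues of a symmetric 3x3 matrix, ascending (e1 <= e2 <= e3).
static inline void eig_sym3(double a11, double a22, double a33,
                            double a12, double a13, double a23,
                            double& e1, double& e2, double& e3) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    e1 = a11; e2 = a22; e3 = a33;
    if (e1 > e2) std::swap(e1, e2);
    if (e2 > e3) std::swap(e2, e3);
    if (e1 > e2) std::swap(e1, e2);
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
  double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
  double detB = c11 * (c22 * c33 - c23 * c23)
              - c12 * (c12 * c33 - c23 * c13)
              + c13 * (c12 * c23 - c22 * c13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  e3 = q + 2.0 * p * std::cos(phi);
  e1 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  e2 = 3.0 * q - e1 - e3;
}

// Tubeness response at scale sigma: Hessian from scale-normalized Gaussian
// derivative kernels; response sqrt(e1*e2) where e1 <= e2 are the two most
// negative eigenvalues, when both are negative (bright tube on dark
// background), else 0. Raw (unnormalized) response is returned.
// [[Rcpp::export(name = ".tubeness_cpp")]]
NumericVector tubeness_cpp(NumericVector vol, IntegerVector dim, double sigma) {
  int d[3] = {dim[0], dim[1], dim[2]};
  long n = (long)d[0] * d[1] * d[2];
  std::vector<double> in(vol.begin(), vol.end());
  std::vector<double> g0 = gauss_kernel(sigma, 0);
  std::vector<double> g1 = gauss_kernel(sigma, 1);
  std::vector<double> g2 = gauss_kernel(sigma, 2);

  // Hessian components via separable passes; kernels per axis (x, y, z).
  std::vector<double> tmp1(n), tmp2(n);
  std::vector<double> H[6]; // xx, yy, zz, xy, xz, yz
  const std::vector<double>* kx[6] = {&g2, &g0, &g0, &g1, &g1, &g0};
  const std::vector<double>* ky[6] = {&g0, &g2, &g0, &g1, &g0, &g1};
  const std::vector<double>* kz[6] = {&g0, &g0, &g2, &g0, &g1, &g1};
  double s2 = sigma * sigma; // scale normalization
  for (int c = 0; c < 6; ++c) {
    conv_axis(in, tmp1, d, *kx[c], 0);
    conv_axis(tmp1, tmp2, d, *ky[c], 1);
    H[c].resize(n);
    conv_axis(tmp2, H[c], d, *kz[c], 2);
    for (long i = 0; i < n; ++i) H[c][i] *= s2;
  }

  NumericVector res(n);
  for (long i = 0; i < n; ++i) {
    double e1, e2, e3;
    eig_sym3(H[0][i], H[1][i], H[2][i], H[3][i], H[4][i], H[5][i], e1, e2, e3);
    res[i] = (e1 < 0.0 && e2 < 0.0) ? std::sqrt(e1 * e2) : 0.0;
  }
  return res;
}
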