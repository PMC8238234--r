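#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Generalized squared-distance transforms (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher).  Works on seed values f: result
//   d(q) = min_p ( |q - p|^2 + f(p) )
// over grid index positions, so with f = 0 on sites / +Inf elsewhere this
// is the exact squared Euclidean distance transform, and with
// f = -r(p)^2 it is the parabolic sphere-envelope used for the
// union-of-spheres lumen reconstruction.

static const double DT_INF = 1e30;

static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= DT_INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DT_INF; z[1] = DT_INF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
          (2.0 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DT_INF; z[1] = DT_INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = DT_INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = DT_INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    d[q] = (double)(q - p) * (q - p) + f[p];
  }
}

// Apply dt1d along one axis of a flattened 3D array (nx,ny,nz), column-major.
static void dt_axis(std::vector<double>& a, int nx, int ny, int nz, int axis) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> f(n), d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  if (axis == 0) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        double* base = a.data() + (size_t)nx * (j + (size_t)ny * k);
        dt1d(base, d.data(), n, v, z);
        std::copy(d.begin(), d.end(), base);
      }
  } else if (axis == 1) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j)
          f[j] = a[i + (size_t)nx * (j + (size_t)ny * k)];
        dt1d(f.data(), d.data(), n, v, z);
        for (int j = 0; j < ny; ++j)
          a[i + (size_t)nx * (j + (size_t)ny * k)] = d[j];
      }
  } else {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k)
          f[k] = a[i + (size_t)nx * (j + (size_t)ny * k)];
        dt1d(f.data(), d.data(), n, v, z);
        for (int k = 0; k < nz; ++k)
          a[i + (size_t)nx * (j + (size_t)ny * k)] = d[k];
      }
  }
}

// [[Rcpp::export(name = ".cpp_gdt")]]
NumericVector cpp_gdt(NumericVector f, IntegerVector dim) {
  int nd = dim.size();
  int nx = dim[0], ny = (nd > 1) ? dim[1] : 1, nz = (nd > 2) ? dim[2] : 1;
  std::vector<double> a(f.begin(), f.end());
  for (size_t i = 0; i < a.size(); ++i)
    if (!R_finite(a[i]) || a[i] >= DT_INF) a[i] = DT_INF;
  dt_axis(a, nx, ny, nz, 0);
  if (ny > 1) dt_axis(a, nx, ny, nz, 1);
  if (nz > 1) dt_axis(a, nx, ny, nz, 2);
  NumericVector out(f.size());
  for (size_t i = 0; i < a.size(); ++i)
    out[i] = (a[i] >= DT_INF) ? R_PosInf : a[i];
  out.attr("dim") = dim;
  return out;
}
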