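#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// boundary: 0 = reflect (mirror about edge voxel), 1 = periodic (wrap)
static inline int wrap_index(int i, int n, int boundary) {
  if (i >= 0 && i < n) return i;
  if (boundary == 1) {
    i %= n;
    if (i < 0) i += n;
    return i;
  }
  // whole-sample mirror: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// convolve every line of a 3D volume along one axis with a 1D kernel
static void conv_axis(const double *in, double *out,
                      const int dim[3], int axis,
                      const double *kern, int radius, int boundary) {
  const int n = dim[axis];
  int oa = (axis == 0) ? 1 : 0;
  int ob = (axis == 2) ? 1 : 2;
  const int na = dim[oa], nb = dim[ob];
  long stride[3];
  stride[0] = 1;
  stride[1] = dim[0];
  stride[2] = (long)dim[0] * dim[1];
  const long s = stride[axis], sa = stride[oa], sb = stride[ob];

  std::vector<double> line(n);
  for (int ib = 0; ib < nb; ++ib) {
    for (int ia = 0; ia < na; ++ia) {
      const long base = ia * sa + ib * sb;
      for (int i = 0; i < n; ++i) line[i] = in[base + i * s];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        if (i - radius >= 0 && i + radius < n) {
          for (int j = -radius; j <= radius; ++j)
            acc += kern[j + radius] * line[i + j];
        } else {
          for (int j = -radius; j <= radius; ++j)
            acc += kern[j + radius] * line[wrap_index(i + j, n, boundary)];
        }
        out[base + i * s] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_separable(NumericVector img, IntegerVector dim,
                                 List kernels, int boundary) {
  if (dim.size() != 3 || kernels.size() != 3)
    stop("expected a 3D volume and three 1D kernels");
  int d[3] = {dim[0], dim[1], dim[2]};
  long nvox = (long)d[0] * d[1] * d[2];
  if ((long)img.size() != nvox) stop("image length does not match dim");

  std::vector<double> buf1(img.begin(), img.end());
  std::vector<double> buf2(nvox);
  double *src = buf1.data(), *dst = buf2.data();
  for (int ax = 0; ax < 3; ++ax) {
    NumericVector k = kernels[ax];
    if (k.size() % 2 == 0) stop("kernel length must be odd");
    int radius = (k.size() - 1) / 2;
    if (radius == 0) {
      if (k[0] != 1.0)
        for (long i = 0; i < nvox; ++i) src[i] *= k[0];
      continue;
    }
    conv_axis(src, dst, d, ax, REAL(k), radius, boundary);
    std::swap(src, dst);
  }
  NumericVector out(nvox);
  std::copy(src, src + nvox, out.begin());
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 neighbourhood filter: type 0 = median (14th of 27), type 1 = mean
// reflect boundary (neighbourhood clipped values mirrored at the edges)
// [[Rcpp::export]]
NumericVector cpp_filter27(NumericVector img, IntegerVector dim, int type) {
  if (dim.size() != 3) stop("expected a 3D volume");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  long nvox = (long)d0 * d1 * d2;
  if ((long)img.size() != nvox) stop("image length does not match dim");
  NumericVector out(nvox);
  const double *in = REAL(img);
  double nb[27];
  for (int i2 = 0; i2 < d2; ++i2) {
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i0 = 0; i0 < d0; ++i0) {
        int m = 0;
        for (int j2 = -1; j2 <= 1; ++j2) {
          int k2 = wrap_index(i2 + j2, d2, 0);
          for (int j1 = -1; j1 <= 1; ++j1) {
            int k1 = wrap_index(i1 + j1, d1, 0);
            for (int j0 = -1; j0 <= 1; ++j0) {
              int k0 = wrap_index(i0 + j0, d0, 0);
              nb[m++] = in[k0 + (long)d0 * (k1 + (long)d1 * k2)];
            }
          }
        }
        long idx = i0 + (long)d0 * (i1 + (long)d1 * i2);
        if (type == 0) {
          std::nth_element(nb, nb + 13, nb + 27);
          out[idx] = nb[13];
        } else {
          double s = 0.0;
          for (int j = 0; j < 27; ++j) s += nb[j];
          out[idx] = s / 27.0;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
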