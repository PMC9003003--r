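#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Reflect index into [0, n-1] (mirror without repeating the edge sample,
// i.e. "reflect" a la scipy mirror for small overshoots).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D correlation with reflect padding. `ker` is applied as a correlation
// (no flip): out[i,j] = sum_{a,b} img[i+a-ci, j+b-cj] * ker[a,b].
// [[Rcpp::export(name = ".conv2_reflect")]]
NumericMatrix conv2_reflect(const NumericMatrix& img, const NumericMatrix& ker) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = ker.nrow(), kc = ker.ncol();
  const int ci = kr / 2, cj = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kc; ++b) {
        const int jj = reflect_idx(j + b - cj, nc);
        for (int a = 0; a < kr; ++a) {
          const int ii = reflect_idx(i + a - ci, nr);
          acc += img(ii, jj) * ker(a, b);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// 2D median filter, square window of half-width `radius`, reflect padding.
// [[Rcpp::export(name = ".median2d")]]
NumericMatrix median2d(const NumericMatrix& img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int w = 2 * radius + 1;
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int b = -radius; b <= radius; ++b) {
        const int jj = reflect_idx(j + b, nc);
        for (int a = -radius; a <= radius; ++a) {
          buf.push_back(img(reflect_idx(i + a, nr), jj));
        }
      }
      const size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
        med = 0.5 * (med + buf[n / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// 3D median filter over an array with dims (n1, n2, n3); half-widths
// (h1, h2, h3); reflect padding on all axes.
// [[Rcpp::export(name = ".median3d")]]
NumericVector median3d(const NumericVector& arr, const int h1, const int h2,
                       const int h3) {
  const IntegerVector dims = arr.attr("dim");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(arr.size());
  out.attr("dim") = dims;
  std::vector<double> buf;
  buf.reserve((size_t)(2 * h1 + 1) * (2 * h2 + 1) * (2 * h3 + 1));
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        buf.clear();
        for (int c = -h3; c <= h3; ++c) {
          const long kk = reflect_idx(k + c, n3);
          for (int b = -h2; b <= h2; ++b) {
            const long jj = reflect_idx(j + b, n2);
            for (int a = -h1; a <= h1; ++a) {
              const long ii = reflect_idx(i + a, n1);
              buf.push_back(arr[ii + n1 * (jj + (long)n2 * kk)]);
            }
          }
        }
        const size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
          med = 0.5 * (med + buf[n / 2 - 1]);
        }
        out[i + n1 * (j + (long)n2 * k)] = med;
      }
    }
  }
  return out;
}

// Rolling-ball background (Sternberg): grayscale opening of the image with
// a ball structuring element of the given radius. Border handling: the
// ball support is clipped to the image (min/max over the valid overlap).
// Returns the background estimate (<= img everywhere in the interior).
// [[Rcpp::export(name = ".rollball_background")]]
NumericMatrix rollball_background(const NumericMatrix& img, const double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  const int w = 2 * r + 1;
  // ball height profile over its disk support; NaN marks off-support
  NumericMatrix ball(w, w);
  for (int b = 0; b < w; ++b) {
    for (int a = 0; a < w; ++a) {
      const double da = a - r, db = b - r;
      const double d2 = da * da + db * db;
      ball(a, b) = (d2 <= radius * radius)
                       ? std::sqrt(radius * radius - d2)
                       : NA_REAL;
    }
  }
  // erosion: E(x) = min over ball support of img(x + t) - ball(t)
  NumericMatrix ero(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int b = 0; b < w; ++b) {
        const int jj = j + b - r;
        if (jj < 0 || jj >= nc) continue;
        for (int a = 0; a < w; ++a) {
          const int ii = i + a - r;
          if (ii < 0 || ii >= nr) continue;
          const double h = ball(a, b);
          if (ISNAN(h)) continue;
          const double v = img(ii, jj) - h;
          if (v < m) m = v;
        }
      }
      ero(i, j) = m;
    }
  }
  // dilation: B(x) = max over ball support of E(x - t) + ball(t)
  NumericMatrix bg(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int b = 0; b < w; ++b) {
        const int jj = j - (b - r);
        if (jj < 0 || jj >= nc) continue;
        for (int a = 0; a < w; ++a) {
          const int ii = i - (a - r);
          if (ii < 0 || ii >= nr) continue;
          const double h = ball(a, b);
          if (ISNAN(h)) continue;
          const double v = ero(ii, jj) + h;
          if (v > m) m = v;
        }
      }
      bg(i, j) = m;
    }
  }
  return bg;
}

// Bilinear shift of a 2D image by (s1, s2) (in units of row/col index);
// out(i, j) = img(i - s1, j - s2), zero outside.
// [[Rcpp::export(name = ".shift_bilinear")]]
NumericMatrix shift_bilinear(const NumericMatrix& img, const double s1,
                             const double s2) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double y = j - s2;
    const int j0 = (int)std::floor(y);
    const double fy = y - j0;
    for (int i = 0; i < nr; ++i) {
      const double x = i - s1;
      const int i0 = (int)std::floor(x);
      const double fx = x - i0;
      double acc = 0.0;
      for (int dj = 0; dj <= 1; ++dj) {
        const int jj = j0 + dj;
        if (jj < 0 || jj >= nc) continue;
        const double wy = dj ? fy : 1.0 - fy;
        for (int di = 0; di <= 1; ++di) {
          const int ii = i0 + di;
          if (ii < 0 || ii >= nr) continue;
          const double wx = di ? fx : 1.0 - fx;
          acc += wx * wy * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
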