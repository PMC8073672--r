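#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflected (edge-duplicating) index: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int p, int n) {
  if (p < 0) return -p - 1;
  if (p >= n) return 2 * n - 1 - p;
  return p;
}

// Per-band 2-D moving median over a w x w spatial window with
// reflected borders.  Exact float median (sorts the window), so the
// result matches a naive sliding-window median bit for bit.
// [[Rcpp::export]]
NumericVector median_filter_cpp(NumericVector cube, int nx, int ny,
                                int nb, int w) {
  if (w < 1 || w % 2 == 0) stop("window must be odd and >= 1");
  const int half = w / 2, wsz = w * w, mid = wsz / 2;
  NumericVector out(cube.size());
  std::vector<double> buf(wsz);
  for (int b = 0; b < nb; ++b) {
    const double* in = &cube[(R_xlen_t)b * nx * ny];
    double* op = &out[(R_xlen_t)b * nx * ny];
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int k = 0;
        for (int dj = -half; dj <= half; ++dj) {
          int jj = reflect_idx(j + dj, ny);
          for (int di = -half; di <= half; ++di) {
            int ii = reflect_idx(i + di, nx);
            buf[k++] = in[ii + (R_xlen_t)jj * nx];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        op[i + (R_xlen_t)j * nx] = buf[mid];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nb);
  return out;
}

// Centred running mean along the band axis, window w (possibly even:
// floor((w-1)/2) bands below, the rest above), reflected ends.
// Long-double accumulation in window order matches base R's sum().
// [[Rcpp::export]]
NumericVector running_band_mean_cpp(NumericVector cube, int nx, int ny,
                                    int nb, int w) {
  if (w < 1) stop("window must be >= 1");
  if (w > nb) stop("window exceeds band count");
  const int lo = (w - 1) / 2, hi = w - 1 - lo;
  const R_xlen_t npix = (R_xlen_t)nx * ny;
  NumericVector out(cube.size());
  for (int b = 0; b < nb; ++b) {
    std::vector<R_xlen_t> offs(w);
    for (int d = -lo; d <= hi; ++d)
      offs[d + lo] = (R_xlen_t)reflect_idx(b + d, nb) * npix;
    double* op = &out[(R_xlen_t)b * npix];
    for (R_xlen_t p = 0; p < npix; ++p) {
      long double acc = 0.0L;
      for (int k = 0; k < w; ++k) acc += cube[offs[k] + p];
      op[p] = (double)(acc / w);
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nb);
  return out;
}

// Convolution along the band axis with a centred odd-length kernel,
// reflected ends (spectral PSF application).
// [[Rcpp::export]]
NumericVector band_convolve_cpp(NumericVector cube, int nx, int ny,
                                int nb, NumericVector kernel) {
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int half = kl / 2;
  const R_xlen_t npix = (R_xlen_t)nx * ny;
  NumericVector out(cube.size());
  for (int b = 0; b < nb; ++b) {
    std::vector<R_xlen_t> offs(kl);
    for (int d = -half; d <= half; ++d)
      offs[d + half] = (R_xlen_t)reflect_idx(b + d, nb) * npix;
    double* op = &out[(R_xlen_t)b * npix];
    for (R_xlen_t p = 0; p < npix; ++p) {
      long double acc = 0.0L;
      for (int k = 0; k < kl; ++k) acc += kernel[k] * cube[offs[k] + p];
      op[p] = (double)acc;
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nb);
  return out;
}
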