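#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Column-wise 1-D convolution with a short kernel, zero-padded at the ends.
// X is bins x pixels; the kernel runs along bins.
// [[Rcpp::export(name = ".conv_cols")]]
NumericMatrix conv_cols(const NumericMatrix& X, const NumericVector& kernel) {
  const int n = X.nrow(), m = X.ncol(), k = kernel.size();
  const int half = k / 2;  // kernel length is odd
  NumericMatrix out(n, m);
  const double* kp = kernel.begin();
  for (int j = 0; j < m; ++j) {
    const double* x = &X[(R_xlen_t)j * n];
    double* y = &out[(R_xlen_t)j * n];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
      const double* kb = kp + (i - lo + half);
      for (int t = lo; t <= hi; ++t) acc += x[t] * kb[lo - t];
      y[i] = acc;
    }
  }
  return out;
}

// van Herk-Gil-Werman running min/max: O(n) per column independent of the
// structuring-element width w (odd); edges are truncated (neutral padding).
static void running_extreme_col(const double* x, double* y, int n, int w, bool maximum) {
  const int half = w / 2;
  const double pad = maximum ? R_NegInf : R_PosInf;
  const int np = n + 2 * half;
  const int nb = (np + w - 1) / w * w;
  std::vector<double> xp(nb, pad), g(nb), h(nb);
  for (int i = 0; i < n; ++i) xp[i + half] = x[i];
  for (int b = 0; b < nb; b += w) {
    g[b] = xp[b];
    for (int i = b + 1; i < b + w; ++i)
      g[i] = maximum ? std::max(g[i - 1], xp[i]) : std::min(g[i - 1], xp[i]);
    h[b + w - 1] = xp[b + w - 1];
    for (int i = b + w - 2; i >= b; --i)
      h[i] = maximum ? std::max(h[i + 1], xp[i]) : std::min(h[i + 1], xp[i]);
  }
  for (int i = 0; i < n; ++i)
    y[i] = maximum ? std::max(h[i], g[i + w - 1]) : std::min(h[i], g[i + w - 1]);
}

// [[Rcpp::export(name = ".erode_cols")]]
NumericMatrix erode_cols(const NumericMatrix& X, int width) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j)
    running_extreme_col(&X[(R_xlen_t)j * n], &out[(R_xlen_t)j * n], n, width, false);
  return out;
}

// [[Rcpp::export(name = ".dilate_cols")]]
NumericMatrix dilate_cols(const NumericMatrix& X, int width) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j)
    running_extreme_col(&X[(R_xlen_t)j * n], &out[(R_xlen_t)j * n], n, width, true);
  return out;
}

// Bilinear sampling of img (rows x cols) at 0-based (x = col, y = row)
// positions; NA outside the frame or when any contributing pixel is NA.
// [[Rcpp::export(name = ".bilinear_sample")]]
NumericVector bilinear_sample(const NumericMatrix& img,
                              const NumericVector& x, const NumericVector& y) {
  const int h = img.nrow(), w = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    if (!R_finite(xi) || !R_finite(yi) ||
        xi < 0.0 || yi < 0.0 || xi > w - 1.0 || yi > h - 1.0) {
      out[i] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    if (x0 == w - 1) --x0;
    if (y0 == h - 1) --y0;
    if (w == 1) x0 = 0;
    if (h == 1) y0 = 0;
    const double fx = xi - x0, fy = yi - y0;
    const int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
    const double* ip = img.begin();
    const double v00 = ip[y0 + (R_xlen_t)x0 * h], v01 = ip[y0 + (R_xlen_t)x1 * h];
    const double v10 = ip[y1 + (R_xlen_t)x0 * h], v11 = ip[y1 + (R_xlen_t)x1 * h];
    if (ISNAN(v00) || ISNAN(v01) || ISNAN(v10) || ISNAN(v11)) {
      out[i] = NA_REAL;
      continue;
    }
    out[i] = v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
             v10 * (1 - fx) * fy + v11 * fx * fy;
  }
  return out;
}

// Nearest-neighbour sampling for integer label maps; returns NA outside.
// [[Rcpp::export(name = ".nearest_sample")]]
IntegerVector nearest_sample(const IntegerMatrix& img,
                             const NumericVector& x, const NumericVector& y) {
  const int h = img.nrow(), w = img.ncol(), n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    if (!R_finite(xi) || !R_finite(yi) ||
        xi < -0.5 || yi < -0.5 || xi > w - 0.5 || yi > h - 0.5) {
      out[i] = NA_INTEGER;
      continue;
    }
    int c = (int)std::lround(xi), r = (int)std::lround(yi);
    c = std::min(std::max(c, 0), w - 1);
    r = std::min(std::max(r, 0), h - 1);
    out[i] = img(r, c);
  }
  return out;
}

// Row-wise maximum of a matrix (used for the base peak spectrum).
// [[Rcpp::export(name = ".row_max")]]
NumericVector row_max(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector out(n, R_NegInf);
  double* o = out.begin();
  for (int j = 0; j < m; ++j) {
    const double* x = &X[(R_xlen_t)j * n];
    for (int i = 0; i < n; ++i)
      if (x[i] > o[i]) o[i] = x[i];
  }
  return out;
}
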