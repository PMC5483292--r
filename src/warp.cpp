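#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at (row y, col x), 0-based continuous coordinates.
// Returns fill when the 2x2 support leaves the image domain.
static inline double bilinear(const NumericMatrix &img, double y, double x,
                              double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  if (x < 0.0 || y < 0.0 || x > nc - 1.0 || y > nr - 1.0) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1, y1 = y0 + 1;
  if (x1 > nc - 1) { x1 = nc - 1; x0 = x1 - 1 < 0 ? 0 : x1 - 1; }
  if (y1 > nr - 1) { y1 = nr - 1; y0 = y1 - 1 < 0 ? 0 : y1 - 1; }
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0), v01 = img(y0, x1);
  double v10 = img(y1, x0), v11 = img(y1, x1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// Pull-convention affine resampling about the image center:
// out(r, c) = in(A %*% p + t) with p = (x, y) centered pixel coordinates.
// m = c(a11, a12, a21, a22, tx, ty).
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericVector m, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  const double a11 = m[0], a12 = m[1], a21 = m[2], a22 = m[3];
  const double tx = m[4], ty = m[5];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double x = c - cx;
    for (int r = 0; r < nr; ++r) {
      const double y = r - cy;
      const double sx = a11 * x + a12 * y + tx + cx;
      const double sy = a21 * x + a22 * y + ty + cy;
      out(r, c) = bilinear(img, sy, sx, fill);
    }
  }
  return out;
}

// Mean absolute temperature difference between the affinely warped moving
// frame and the fixed frame, over the pixels listed in mask_rows/mask_cols
// (0-based). Out-of-domain source samples take the fill temperature.
// [[Rcpp::export]]
double affine_mad_cpp(NumericMatrix moving, NumericMatrix fixed,
                      IntegerVector mask_rows, IntegerVector mask_cols,
                      NumericVector m, double fill) {
  const int nr = moving.nrow(), nc = moving.ncol();
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  const double a11 = m[0], a12 = m[1], a21 = m[2], a22 = m[3];
  const double tx = m[4], ty = m[5];
  const int n = mask_rows.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const int r = mask_rows[i], c = mask_cols[i];
    const double x = c - cx, y = r - cy;
    const double sx = a11 * x + a12 * y + tx + cx;
    const double sy = a21 * x + a22 * y + ty + cy;
    acc += std::fabs(bilinear(moving, sy, sx, fill) - fixed(r, c));
  }
  return n > 0 ? acc / n : NA_REAL;
}
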