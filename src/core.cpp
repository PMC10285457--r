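#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mirror-reflect an index into [0, n): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D correlation (filter) with mirror-reflected borders; odd-sized kernel.
// [[Rcpp::export]]
NumericMatrix cpp_filter2_reflect(NumericMatrix img, NumericMatrix kern) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = kern.nrow(), kc = kern.ncol();
  int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = 0; dj < kc; ++dj) {
        int cj = reflect_idx(j + dj - hc, nc);
        for (int di = 0; di < kr; ++di) {
          int ci = reflect_idx(i + di - hr, nr);
          acc += img(ci, cj) * kern(di, dj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable Gaussian blur, mirror-reflected borders. sigma in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)      // along rows (vertical)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += img(reflect_idx(i + d, nr), j) * k[d + rad];
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)      // along columns (horizontal)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += tmp(i, reflect_idx(j + d, nc)) * k[d + rad];
      out(i, j) = acc;
    }
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample at 0-based pixel coords (x = column, y = row), border clamp.
static inline double bilin(const NumericMatrix &img, double x, double y) {
  int nr = img.nrow(), nc = img.ncol();
  x = clampd(x, 0.0, nc - 1.0);
  y = clampd(y, 0.0, nr - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > nc - 2) x0 = nc - 2;
  if (y0 > nr - 2) y0 = nr - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x0 + 1) * fx * (1 - fy) +
         img(y0 + 1, x0) * (1 - fx) * fy + img(y0 + 1, x0 + 1) * fx * fy;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bilin(img, x[i], y[i]);
  return out;
}

// Demons-style increment estimation for one frame pair at sparse points.
// I0, I1: pre-smoothed intensity images; px, py: 0-based pixel coords of the
// points in frame t; u0x, u0y: initial displacement guess (px). For each
// point, the update force is averaged over a square patch of side `patch`:
//   du = mean_patch[ (I0 - I1(x+u)) * grad(I0) / (|grad(I0)|^2 + alpha*(I0-I1)^2) ]
// iterated until max |du| < tol or max_iter. Points whose patch would fall
// fully outside the image keep their initial guess (flagged in `ok`).
// [[Rcpp::export]]
List cpp_demons_pair(NumericMatrix I0, NumericMatrix I1,
                     NumericVector px, NumericVector py,
                     NumericVector u0x, NumericVector u0y,
                     int patch, double alpha, int max_iter, double tol) {
  int n = px.size();
  int nr = I0.nrow(), nc = I0.ncol();
  int half = patch / 2;
  int np = patch * patch;
  // central-difference gradient of I0 (pixel units)
  NumericMatrix Gx(nr, nc), Gy(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int jm = reflect_idx(j - 1, nc), jp = reflect_idx(j + 1, nc);
      int im = reflect_idx(i - 1, nr), ip = reflect_idx(i + 1, nr);
      Gx(i, j) = 0.5 * (I0(i, jp) - I0(i, jm));
      Gy(i, j) = 0.5 * (I0(ip, j) - I0(im, j));
    }
  NumericVector ux(n), uy(n);
  LogicalVector ok(n);
  std::vector<double> p0(np), gx(np), gy(np), cx(np), cy(np);
  for (int q = 0; q < n; ++q) {
    double x = px[q], y = py[q];
    ux[q] = u0x[q];
    uy[q] = u0y[q];
    if (x < -half || x > nc - 1 + half || y < -half || y > nr - 1 + half) {
      ok[q] = false;  // point has left the image
      continue;
    }
    ok[q] = true;
    int m = 0;
    for (int dj = -half; dj <= half; ++dj)
      for (int di = -half; di <= half; ++di) {
        double sx = x + dj, sy = y + di;
        if (sx < 0 || sx > nc - 1 || sy < 0 || sy > nr - 1) continue;
        cx[m] = sx;
        cy[m] = sy;
        p0[m] = bilin(I0, sx, sy);
        gx[m] = bilin(Gx, sx, sy);
        gy[m] = bilin(Gy, sx, sy);
        ++m;
      }
    if (m == 0) { ok[q] = false; continue; }
    for (int it = 0; it < max_iter; ++it) {
      double sx = 0.0, sy_ = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = p0[k] - bilin(I1, cx[k] + ux[q], cy[k] + uy[q]);
        double den = gx[k] * gx[k] + gy[k] * gy[k] + alpha * diff * diff;
        if (den > 1e-9) {
          sx += diff * gx[k] / den;
          sy_ += diff * gy[k] / den;
        }
      }
      double dux = sx / m, duy = sy_ / m;
      ux[q] += dux;
      uy[q] += duy;
      if (std::fabs(dux) < tol && std::fabs(duy) < tol) break;
    }
  }
  return List::create(_["ux"] = ux, _["uy"] = uy, _["ok"] = ok);
}

// Bilinear splatting of weighted point scatterers onto an nr x nc pixel grid.
// x, y are 0-based pixel coords; mass falling outside the grid is dropped.
// [[Rcpp::export]]
NumericMatrix cpp_splat_bilinear(int nr, int nc, NumericVector x,
                                 NumericVector y, NumericVector w) {
  NumericMatrix out(nr, nc);
  int n = x.size();
  for (int q = 0; q < n; ++q) {
    double xx = x[q], yy = y[q];
    int x0 = (int)std::floor(xx), y0 = (int)std::floor(yy);
    double fx = xx - x0, fy = yy - y0;
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int r = y0 + di, c = x0 + dj;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        double wt = (dj ? fx : 1 - fx) * (di ? fy : 1 - fy);
        out(r, c) += w[q] * wt;
      }
  }
  return out;
}
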