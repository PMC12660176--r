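#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling (trailing-window, inclusive of current sample) quantile of each row
// of x, where rows are pixel time series and columns are frames. Quantile uses
// linear interpolation between order statistics (R type 7) so results match
// stats::quantile() on the same window. The first window-1 columns are
// backfilled with the first full-window value, so early frames are judged
// against the window-wide level rather than against themselves.
// [[Rcpp::export]]
NumericMatrix cpp_roll_quantile(const NumericMatrix& x, int window, double prob) {
  const int npx = x.nrow(), nt = x.ncol();
  if (window < 1) stop("window must be >= 1");
  if (prob < 0.0 || prob > 1.0) stop("prob must be in [0, 1]");
  NumericMatrix out(npx, nt);
  std::vector<double> buf;
  buf.reserve(window + 1);
  for (int p = 0; p < npx; ++p) {
    buf.clear();
    for (int t = 0; t < nt; ++t) {
      const double v = x(p, t);
      buf.insert(std::upper_bound(buf.begin(), buf.end(), v), v);
      if ((int)buf.size() > window) {
        const double old = x(p, t - window);
        buf.erase(std::lower_bound(buf.begin(), buf.end(), old));
      }
      const int m = (int)buf.size();
      const double h = prob * (m - 1);
      const int lo = (int)std::floor(h);
      const int hi = lo + 1 < m ? lo + 1 : lo;
      out(p, t) = buf[lo] + (h - lo) * (buf[hi] - buf[lo]);
    }
    if (nt >= window) {
      for (int t = 0; t < window - 1; ++t) out(p, t) = out(p, window - 1);
    }
  }
  return out;
}

// Separable Gaussian smoothing of every frame of a ny x nx x nt array
// (replicate padding at the borders). Kernel radius = ceil(3*sigma).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth_frames(const NumericVector& arr, int ny, int nx,
                                      int nt, double sigma) {
  if (sigma <= 0) stop("sigma must be > 0");
  if ((R_xlen_t)ny * nx * nt != arr.size()) stop("dims do not match array length");
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& kv : k) kv /= s;
  NumericVector out(arr.size());
  std::vector<double> tmp((size_t)ny * nx);
  for (int t = 0; t < nt; ++t) {
    const double* f = &arr[(R_xlen_t)t * ny * nx];
    double* o = &out[(R_xlen_t)t * ny * nx];
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int yy = y + i;
          if (yy < 0) yy = 0;
          if (yy >= ny) yy = ny - 1;
          acc += k[i + r] * f[yy + (size_t)x * ny];
        }
        tmp[y + (size_t)x * ny] = acc;
      }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int xx = x + i;
          if (xx < 0) xx = 0;
          if (xx >= nx) xx = nx - 1;
          acc += k[i + r] * tmp[y + (size_t)xx * ny];
        }
        o[y + (size_t)x * ny] = acc;
      }
  }
  out.attr("dim") = IntegerVector::create(ny, nx, nt);
  return out;
}

// 8-connected component labelling of a logical mask; labels are assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(y + x * ny);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cy = idx % ny, cx = idx / ny;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = cy + dy, xx = cx + dx;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              stack.push_back(yy + xx * ny);
            }
          }
      }
    }
  return lab;
}

// 8-neighbour local maxima of img at or above thresh. Plateaus are counted
// once: a pixel qualifies if it is strictly greater than every neighbour that
// precedes it in column-major scan order and >= every later neighbour.
// Returns a 3-column matrix (row, col, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(const NumericMatrix& img, double thresh) {
  const int ny = img.nrow(), nx = img.ncol();
  std::vector<double> rr, cc, vv;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const double v = img(y, x);
      if (!(v >= thresh)) continue;
      bool ismax = true;
      for (int dx = -1; dx <= 1 && ismax; ++dx)
        for (int dy = -1; dy <= 1 && ismax; ++dy) {
          if (dx == 0 && dy == 0) continue;
          const int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          const double u = img(yy, xx);
          const bool earlier = (dx < 0) || (dx == 0 && dy < 0);
          if (earlier ? (u >= v) : (u > v)) ismax = false;
        }
      if (ismax) {
        rr.push_back(y + 1);
        cc.push_back(x + 1);
        vv.push_back(v);
      }
    }
  NumericMatrix out((int)rr.size(), 3);
  for (int i = 0; i < (int)rr.size(); ++i) {
    out(i, 0) = rr[i];
    out(i, 1) = cc[i];
    out(i, 2) = vv[i];
  }
  colnames(out) = CharacterVector::create("row", "col", "value");
  return out;
}

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
    m = 0.5 * (m + v[mid - 1]);
  }
  return m;
}

// Per-row median and median absolute deviation (scaled by 1.4826 for normal
// consistency) of x; rows are pixel time series. Used as robust per-pixel
// centre and noise estimates that ignore sparse flashes.
// [[Rcpp::export]]
NumericMatrix cpp_row_medmad(const NumericMatrix& x) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, 2);
  std::vector<double> v((size_t)m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) v[j] = x(i, j);
    const double med = median_of(v);
    for (int j = 0; j < m; ++j) v[j] = std::fabs(x(i, j) - med);
    out(i, 0) = med;
    out(i, 1) = 1.4826 * median_of(v);
  }
  colnames(out) = CharacterVector::create("median", "mad");
  return out;
}
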