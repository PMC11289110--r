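#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by breadth-first search.
// Labels are assigned 1..n in column-major scan order of each component's
// first-encountered pixel, so the labeling is deterministic for a given
// mask and connectivity.
// [[Rcpp::export]]
IntegerMatrix cw_label(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Even-odd (crossing-number) polygon scan fill evaluated at pixel centers.
// Pixel (r, c), 0-based, has center (x = c + 0.5, y = r + 0.5); a pixel is
// set when its center lies inside the polygon. The half-open crossing test
// (yi > y) != (yj > y) with a strict x comparison yields a consistent
// top-left-style convention for centers exactly on edges.
// [[Rcpp::export]]
LogicalMatrix cw_fill_polygon(const NumericVector& xs, const NumericVector& ys,
                              int height, int width) {
  const int n = xs.size();
  LogicalMatrix out(height, width);
  if (n < 3) return out;
  double xmin = xs[0], xmax = xs[0], ymin = ys[0], ymax = ys[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
    ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
  }
  int c0 = std::max(0, (int)std::floor(xmin - 0.5));
  int c1 = std::min(width - 1, (int)std::ceil(xmax));
  int r0 = std::max(0, (int)std::floor(ymin - 0.5));
  int r1 = std::min(height - 1, (int)std::ceil(ymax));
  for (int r = r0; r <= r1; ++r) {
    double y = r + 0.5;
    for (int c = c0; c <= c1; ++c) {
      double x = c + 0.5;
      bool inside = false;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        if ((ys[i] > y) != (ys[j] > y)) {
          double xint = (xs[j] - xs[i]) * (y - ys[i]) / (ys[j] - ys[i]) + xs[i];
          if (x < xint) inside = !inside;
        }
      }
      if (inside) out(r, c) = true;
    }
  }
  return out;
}

// Joint label histogram: counts of pixels carrying each (pred, gt) label
// pair with both labels > 0, plus per-label pixel areas. Used to build the
// candidate overlap pairs for cyst matching in one pass.
// [[Rcpp::export]]
List cw_overlap_counts(const IntegerMatrix& predLab, const IntegerMatrix& gtLab,
                       int nPred, int nGt) {
  std::vector<double> inter((size_t)nPred * nGt, 0.0);
  std::vector<double> pArea(nPred, 0.0), gArea(nGt, 0.0);
  const int n = predLab.size();
  for (int i = 0; i < n; ++i) {
    int p = predLab[i], g = gtLab[i];
    if (p > 0) pArea[p - 1] += 1;
    if (g > 0) gArea[g - 1] += 1;
    if (p > 0 && g > 0) inter[(size_t)(p - 1) + (size_t)nPred * (g - 1)] += 1;
  }
  NumericMatrix im(nPred, nGt);
  for (size_t i = 0; i < inter.size(); ++i) im[i] = inter[i];
  return List::create(_["intersection"] = im,
                      _["predAreas"] = NumericVector(pArea.begin(), pArea.end()),
                      _["gtAreas"] = NumericVector(gArea.begin(), gArea.end()));
}

// im2col for k x k "same" convolution with zero padding (k odd).
// Input x is an H x W x C array (column-major). Output has one row per
// pixel (column-major pixel order r + c*H) and k*k*C columns ordered
// ch-major: col = ch*k*k + j*k + i, offsets i (rows), j (cols) in 0..k-1.
// [[Rcpp::export]]
NumericMatrix cw_im2col(const NumericVector& x, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  NumericMatrix out(H * W, k * k * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = &x[(size_t)ch * H * W];
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int col = ch * k * k + j * k + i;
        double* oc = &out[(size_t)col * H * W];
        const int roff = i - p, coff = j - p;
        for (int c = 0; c < W; ++c) {
          int sc = c + coff;
          if (sc < 0 || sc >= W) continue;
          int rlo = std::max(0, -roff), rhi = std::min(H, H - roff);
          const double* src = xc + (size_t)sc * H + roff;
          double* dst = oc + (size_t)c * H;
          for (int r = rlo; r < rhi; ++r) dst[r] = src[r];
        }
      }
    }
  }
  return out;
}

// Adjoint of cw_im2col: scatter-add columns back into an H x W x C array.
// [[Rcpp::export]]
NumericVector cw_col2im(const NumericMatrix& cols, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  NumericVector out((size_t)H * W * C);
  for (int ch = 0; ch < C; ++ch) {
    double* xc = &out[(size_t)ch * H * W];
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int col = ch * k * k + j * k + i;
        const double* oc = &cols[(size_t)col * H * W];
        const int roff = i - p, coff = j - p;
        for (int c = 0; c < W; ++c) {
          int sc = c + coff;
          if (sc < 0 || sc >= W) continue;
          int rlo = std::max(0, -roff), rhi = std::min(H, H - roff);
          double* dst = xc + (size_t)sc * H + roff;
          const double* src = oc + (size_t)c * H;
          for (int r = rlo; r < rhi; ++r) dst[r] += src[r];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 2x2 max pooling with stride 2 (H, W even). Returns the pooled array and
// the 1-based linear index into x of each selected maximum, for backprop.
// [[Rcpp::export]]
List cw_maxpool(const NumericVector& x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector arg((size_t)Ho * Wo * C);
  for (int ch = 0; ch < C; ++ch) {
    const size_t xoff = (size_t)ch * H * W, yoff = (size_t)ch * Ho * Wo;
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        size_t base = xoff + (size_t)(2 * c) * H + 2 * r;
        size_t best = base;
        double bv = x[base];
        const size_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
        y[yoff + (size_t)c * Ho + r] = bv;
        arg[yoff + (size_t)c * Ho + r] = (int)best + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cw_maxpool_bwd(const NumericVector& dy, const IntegerVector& argmax,
                             int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  for (int i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
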