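#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element given as parallel
// offset/height vectors: out(x) = min_s [ f(x+s) - b(s) ] over in-bounds s.
// Out-of-bounds offsets are skipped (domain-restricted adjunction), which
// keeps the derived opening anti-extensive and idempotent.
// Offset-outer loop order keeps both arrays in sequential (column-major)
// access, which matters at ball radii of ~50 px (thousands of offsets).
// [[Rcpp::export]]
NumericMatrix cpp_erode(NumericMatrix img, IntegerVector dr, IntegerVector dc,
                        NumericVector height) {
  int H = img.nrow(), W = img.ncol(), K = dr.size();
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), R_PosInf);
  const double *f = img.begin();
  double *o = out.begin();
  for (int k = 0; k < K; ++k) {
    int a = dr[k], b = dc[k];
    double h = height[k];
    int i0 = std::max(0, -a), i1 = std::min(H, H - a);
    int j0 = std::max(0, -b), j1 = std::min(W, W - b);
    for (int j = j0; j < j1; ++j) {
      const double *src = f + (j + b) * H + a;
      double *dst = o + j * H;
      for (int i = i0; i < i1; ++i) {
        double v = src[i] - h;
        if (v < dst[i]) dst[i] = v;
      }
    }
  }
  return out;
}

// Adjoint dilation: out(x) = max_s [ f(x-s) + b(s) ].
// [[Rcpp::export]]
NumericMatrix cpp_dilate(NumericMatrix img, IntegerVector dr, IntegerVector dc,
                         NumericVector height) {
  int H = img.nrow(), W = img.ncol(), K = dr.size();
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), R_NegInf);
  const double *f = img.begin();
  double *o = out.begin();
  for (int k = 0; k < K; ++k) {
    int a = -dr[k], b = -dc[k];
    double h = height[k];
    int i0 = std::max(0, -a), i1 = std::min(H, H - a);
    int j0 = std::max(0, -b), j1 = std::min(W, W - b);
    for (int j = j0; j < j1; ++j) {
      const double *src = f + (j + b) * H + a;
      double *dst = o + j * H;
      for (int i = i0; i < i1; ++i) {
        double v = src[i] + h;
        if (v > dst[i]) dst[i] = v;
      }
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask; labels are assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
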