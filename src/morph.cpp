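#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element.
// offsets: K x 2 integer matrix of (dr, dc); heights: K-vector of SE heights.
// The neighbourhood is restricted to pixels inside the image, so a constant
// image erodes to (c - max height) everywhere, including at the borders
// (the centre offset (0,0) must be part of the SE).
// [[Rcpp::export]]
NumericMatrix morph_erode(const NumericMatrix& x, const IntegerMatrix& offsets,
                          const NumericVector& heights) {
  const int nr = x.nrow(), nc = x.ncol(), K = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        const int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = x(rr, cc) - heights[k];
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Grayscale dilation with a non-flat structuring element (adjoint of
// morph_erode for a symmetric SE).
// [[Rcpp::export]]
NumericMatrix morph_dilate(const NumericMatrix& x, const IntegerMatrix& offsets,
                           const NumericVector& heights) {
  const int nr = x.nrow(), nc = x.ncol(), K = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = x(rr, cc) + heights[k];
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Connected-component labelling of a logical mask with 4- or 8-neighbour
// connectivity. Labels are assigned in column-major scan order of the first
// pixel encountered, so the labelling is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int K = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int k = 0; k < K; ++k) {
          const int rr = pr + dr8[k], cc = pc + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          stack.push_back(rr + cc * nr);
        }
      }
    }
  }
  return lab;
}
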