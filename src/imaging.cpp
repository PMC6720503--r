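#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median over a disc neighbourhood given by (dy, dx) offsets; pixels whose
// neighbourhood is cut by the border use the reduced neighbourhood.
// [[Rcpp::export]]
IntegerMatrix median_disc_cpp(IntegerMatrix img, IntegerVector dy, IntegerVector dx) {
  int nr = img.nrow(), nc = img.ncol(), k = dy.size();
  IntegerMatrix out(nr, nc);
  std::vector<int> buf;
  buf.reserve(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int o = 0; o < k; ++o) {
        int y = i + dy[o], x = j + dx[o];
        if (y >= 0 && y < nr && x >= 0 && x < nc) buf.push_back(img(y, x));
      }
      int n = buf.size();
      int mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      int m = buf[mid];
      if (n % 2 == 0) {
        // lower half's max for the even case -> average, rounded half up
        int lo = *std::max_element(buf.begin(), buf.begin() + mid);
        m = (lo + m + 1) / 2;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask (two-pass BFS).
// Returns an integer matrix of labels, 0 = background, 1..n = components.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int py = p % nr, px = p / nr;
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dy == 0 && dx == 0) continue;
            int y = py + dy, x = px + dx;
            if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
            if (mask(y, x) && lab(y, x) == 0) {
              lab(y, x) = next;
              stack.push_back(y + x * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
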