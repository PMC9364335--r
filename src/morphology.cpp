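#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

// Greyscale erosion/dilation with a flat disc structuring element,
// decomposed into horizontal row segments. For each distinct segment
// half-width the horizontal sliding-window extremum is computed in O(n)
// with a monotonic deque, then accumulated across vertical offsets.
// Pixels outside the image are ignored (no padding value), matching the
// behavior of a background estimate that never reaches beyond the frame.

static void row_extremum(const std::vector<double>& in, int n, int hw,
                         bool erode, std::vector<double>& out) {
  std::deque<int> q;
  int j = 0;
  for (int i = 0; i < n + hw; ++i) {
    if (i < n) {
      while (!q.empty() &&
             (erode ? in[q.back()] >= in[i] : in[q.back()] <= in[i]))
        q.pop_back();
      q.push_back(i);
    }
    j = i - hw;  // output index whose window [j-hw, j+hw] ends at i
    if (j >= 0) {
      while (q.front() < j - hw) q.pop_front();
      out[j] = in[q.front()];
    }
  }
}

static NumericMatrix disc_filter(const NumericMatrix& m, int radius,
                                 bool erode) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix res(nr, nc);
  std::fill(res.begin(), res.end(),
            erode ? R_PosInf : R_NegInf);
  // group vertical offsets by their segment half-width
  std::vector<std::vector<int>> by_hw(radius + 1);
  for (int dy = -radius; dy <= radius; ++dy) {
    int hw = (int)std::floor(std::sqrt((double)radius * radius -
                                       (double)dy * dy) + 1e-9);
    by_hw[hw].push_back(dy);
  }
  std::vector<double> rowin(nc), rowout(nc);
  NumericMatrix horiz(nr, nc);
  for (int hw = 0; hw <= radius; ++hw) {
    if (by_hw[hw].empty()) continue;
    // horizontal pass at this half-width
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowin[j] = m(i, j);
      if (hw == 0) {
        for (int j = 0; j < nc; ++j) horiz(i, j) = rowin[j];
      } else {
        row_extremum(rowin, nc, hw, erode, rowout);
        for (int j = 0; j < nc; ++j) horiz(i, j) = rowout[j];
      }
    }
    // accumulate each vertical offset using this half-width
    for (int dy : by_hw[hw]) {
      for (int j = 0; j < nc; ++j) {
        int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
        for (int i = i0; i < i1; ++i) {
          double v = horiz(i + dy, j);
          if (erode ? v < res(i, j) : v > res(i, j)) res(i, j) = v;
        }
      }
    }
  }
  return res;
}

// [[Rcpp::export(name = ".grey_erode_disc")]]
NumericMatrix grey_erode_disc(NumericMatrix m, int radius) {
  return disc_filter(m, radius, true);
}

// [[Rcpp::export(name = ".grey_dilate_disc")]]
NumericMatrix grey_dilate_disc(NumericMatrix m, int radius) {
  return disc_filter(m, radius, false);
}
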