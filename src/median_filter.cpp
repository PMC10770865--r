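#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One pass of a k x k median filter with edge-replication padding.
// [[Rcpp::export]]
NumericMatrix median_filter_pass(const NumericMatrix& img, int kernel) {
  const int h = img.nrow(), w = img.ncol(), r = kernel / 2;
  NumericMatrix out(h, w);
  std::vector<double> win;
  win.reserve((size_t)kernel * kernel);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      win.clear();
      for (int dx = -r; dx <= r; ++dx) {
        int xs = std::min(std::max(x + dx, 0), w - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int ys = std::min(std::max(y + dy, 0), h - 1);
          win.push_back(img(ys, xs));
        }
      }
      size_t mid = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      double m = win[mid];
      if (win.size() % 2 == 0) {
        // even window (never hit for odd kernels, kept for safety):
        // average the two central order statistics
        double lo = *std::max_element(win.begin(), win.begin() + mid);
        m = 0.5 * (lo + m);
      }
      out(y, x) = m;
    }
  }
  return out;
}
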