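#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Largest axis-aligned all-true rectangle in a logical matrix.
// Per-row histogram of consecutive true pixels ending at that row, largest
// rectangle in each histogram via a monotonic stack of (start, height)
// pairs. Ties in area broken by smallest y0, then smallest x0. Returns
// (x0, y0, x1, y1, area), 0-based half-open bounds.
// [[Rcpp::export]]
NumericVector max_rect_stack(const LogicalMatrix &m) {
  const int h = m.nrow(), w = m.ncol();
  std::vector<int> height(w, 0);
  std::vector<int> spos, shgt;  // stack: start column, bar height
  spos.reserve(w + 1); shgt.reserve(w + 1);
  long best_area = 0;
  int bx0 = 0, by0 = 0, bx1 = 0, by1 = 0;

  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) height[x] = m(y, x) ? height[x] + 1 : 0;
    spos.clear(); shgt.clear();
    for (int x = 0; x <= w; ++x) {
      const int cur = (x < w) ? height[x] : 0;
      int start = x;
      while (!shgt.empty() && shgt.back() > cur) {
        const int hh = shgt.back();
        const int pos = spos.back();
        shgt.pop_back(); spos.pop_back();
        const long area = (long)hh * (x - pos);
        const int y0 = y - hh + 1;
        if (area > best_area ||
            (area == best_area && area > 0 &&
             (y0 < by0 || (y0 == by0 && pos < bx0)))) {
          best_area = area;
          bx0 = pos; by0 = y0; bx1 = x; by1 = y + 1;
        }
        start = pos;  // a shorter bar extends back over the popped span
      }
      if (x < w && cur > 0 && (shgt.empty() || shgt.back() < cur)) {
        spos.push_back(start); shgt.push_back(cur);
      }
    }
  }
  return NumericVector::create(bx0, by0, bx1, by1, (double)best_area);
}
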