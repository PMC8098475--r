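#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflected (symmetric) boundary index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Per-pixel median over a k x k window with reflected padding.
// Non-finite values are ignored; a window with no finite value gives NA.
// [[Rcpp::export]]
NumericMatrix median_filter_reflect(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be odd and >= 1");
  const int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          const int ii = reflect(i + di, nr);
          const double v = x(ii, jj);
          if (R_finite(v)) buf.push_back(v);
        }
      }
      const size_t n = buf.size();
      if (n == 0) {
        out(i, j) = NA_REAL;
      } else {
        const size_t mid = n / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double m = buf[mid];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          m = 0.5 * (m + lo);
        }
        out(i, j) = m;
      }
    }
  }
  return out;
}
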